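# Outcome metrics: accuracy, bias and coancestry of top-ranked candidates.

.align_gebv <- function(gebv, tbv, ids) {
  if (inherits(gebv, "gebv_result")) gebv <- gebv$gebv
  if (!is.null(ids)) {
    gebv <- gebv[match(as.character(ids), names(gebv))]
    tbv <- if (!is.null(names(tbv))) tbv[match(as.character(ids), names(tbv))]
           else tbv[ids]
  }
  if (anyNA(gebv) || anyNA(tbv)) stop("GEBV/TBV missing for some ids")
  list(g = as.numeric(gebv), t = as.numeric(tbv))
}

#' Accuracy of GEBV
#'
#' Pearson correlation between GEBV and true breeding values over the
#' phenotyped offspring.
#'
#' @param gebv A `gebv_result` or named numeric vector.
#' @param tbv Named numeric vector of true breeding values.
#' @param ids Ids over which to compute the correlation (default: the
#'   intersection implied by the names of `gebv`).
#' @return Scalar correlation.
#' @export
accuracy <- function(gebv, tbv, ids = NULL) {
  v <- .align_gebv(gebv, tbv, ids)
  if (length(v$g) < 2) stop("need at least two animals")
  if (sd(v$g) == 0) stop("GEBV are constant; accuracy undefined")
  if (sd(v$t) == 0) stop("TBV are constant; accuracy undefined")
  cor(v$g, v$t)
}

#' Bias of GEBV (dispersion)
#'
#' Ordinary least-squares regression slope of true breeding values on
#' GEBV; a slope of 1 indicates unbiased dispersion.
#'
#' @inheritParams accuracy
#' @return Scalar regression slope.
#' @export
bias_regression <- function(gebv, tbv, ids = NULL) {
  v <- .align_gebv(gebv, tbv, ids)
  vg <- var(v$g)
  if (!is.finite(vg) || vg == 0) stop("GEBV variance is zero")
  stats::cov(v$g, v$t) / vg
}

#' Coancestry among top-ranked selection candidates
#'
#' Selects the `n_males` top males and `n_females` top females by GEBV
#' among the candidate ids (ties broken by ascending animal id) and
#' returns the mean realized genomic relationship over all unordered
#' distinct pairs of the selected set (diagonal excluded).
#'
#' @param grm A full `grm`.
#' @param gebv A `gebv_result` or named vector.
#' @param pedigree Pedigree data.frame supplying the sexes.
#' @param candidate_ids Selection pool (typically the phenotyped
#'   offspring).
#' @param n_males,n_females Numbers selected per sex.
#' @return Scalar mean relationship among the selected animals.
#' @export
coancestry_top <- function(grm, gebv, pedigree, candidate_ids,
                           n_males = 20L, n_females = 200L) {
  if (inherits(gebv, "gebv_result")) gebv <- gebv$gebv
  g <- gebv[match(as.character(candidate_ids), names(gebv))]
  if (anyNA(g)) stop("GEBV missing for some candidates")
  sex <- pedigree$sex[match(candidate_ids, pedigree$id)]
  top <- function(s, k) {
    pool <- candidate_ids[sex == s]
    if (length(pool) < k)
      stop(sprintf("only %d candidates of sex %s; %d needed",
                   length(pool), s, k))
    gp <- g[sex == s]
    pool[order(-gp, pool)][seq_len(k)]
  }
  sel <- c(top("M", n_males), top("F", n_females))
  B <- .g_submatrix(grm, sel)
  mean(B[upper.tri(B)])
}
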