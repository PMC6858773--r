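# VanRaden method-1 genomic relationship matrix and relationship summaries.

.new_grm <- function(kind, ids, p, denom, G = NULL, blocks = NULL) {
  structure(list(kind = kind, ids = as.integer(ids), p = p, denom = denom,
                 G = G, blocks = blocks),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %s, %d animals, %d markers, denominator %.3f\n",
              x$kind, length(x$ids), length(x$p), x$denom))
  invisible(x)
}

#' Allele frequencies from a dosage matrix
#'
#' `p_j` is the frequency of the counted (A2) allele at marker `j`,
#' computed as half the mean dosage over all animals in the matrix
#' (sires, dams and offspring alike).
#'
#' @param dosages Numeric matrix, animals in rows, markers in columns,
#'   entries 0/1/2.
#' @param impute Policy for missing dosages: `"error"` (default) or
#'   `"mean"` for per-marker mean imputation.
#' @return Numeric vector of frequencies in \[0, 1\].
#' @export
allele_frequencies <- function(dosages, impute = c("error", "mean")) {
  impute <- match.arg(impute)
  if (anyNA(dosages)) {
    if (impute == "error")
      stop("missing dosages; set impute = \"mean\" to mean-impute")
    cm <- colMeans(dosages, na.rm = TRUE)
    na <- which(is.na(dosages), arr.ind = TRUE)
    dosages[na] <- cm[na[, 2]]
  }
  colMeans(dosages) / 2
}

#' Build the VanRaden method-1 genomic relationship matrix
#'
#' `G = MM' / (2 * sum(p_j (1 - p_j)))` where `M` is the dosage matrix
#' centered by column as `dosage - 2 p_j`. When `p` is NULL the
#' frequencies are computed from `dosages` itself, which makes the grand
#' sum of `G` zero.
#'
#' @param dosages Numeric matrix, animals x markers (0/1/2; row names are
#'   used as animal ids when present).
#' @param p Optional allele frequencies; default computed from `dosages`.
#' @param ids Animal ids (default: row names or row indices).
#' @param keep_M Keep the centered dosage matrix in the result.
#' @return Object of class `grm` with elements `G`, `p`, `denom`, `ids`
#'   (and `M` if requested).
#' @export
build_grm <- function(dosages, p = NULL, ids = NULL, keep_M = FALSE) {
  if (is.null(p)) p <- allele_frequencies(dosages)
  stopifnot(length(p) == ncol(dosages))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are fixed: VanRaden denominator is zero")
  if (is.null(ids))
    ids <- if (!is.null(rownames(dosages))) as.integer(rownames(dosages))
           else seq_len(nrow(dosages))
  M <- sweep(dosages, 2L, 2 * p)
  G <- tcrossprod(M) / denom
  dimnames(G) <- NULL
  out <- .new_grm("full", ids, p, denom, G = G)
  if (keep_M) out$M <- M
  out
}

#' Genomic relationship matrix for a simulated population
#'
#' Fast path over the raw haplotypes of a [nested_mating()] population.
#' Marker loci only enter G; allele frequencies are computed from all
#' animals (parents and offspring). `mode = "sire_blocks"` computes only
#' the per-sire-family diagonal blocks over offspring — sufficient for
#' relationship distributions and within-family grouping at a fraction of
#' the cost of the full matrix.
#'
#' @param pop A `population`.
#' @param mode `"full"` or `"sire_blocks"`.
#' @return Object of class `grm`; `kind` records the mode. Block GRMs
#'   hold `blocks`, a list per sire of `list(ids, G)`.
#' @export
grm_from_population <- function(pop, mode = c("full", "sire_blocks")) {
  mode <- match.arg(mode)
  markers <- which(pop$map$role == "marker")
  p <- freq_cpp(pop$haps, markers)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are fixed: VanRaden denominator is zero")
  if (mode == "full") {
    M <- centered_dosage_cpp(pop$haps, as.integer(pop$ids), markers, p)
    G <- crossprod(M) / denom
    return(.new_grm("full", pop$ids, p, denom, G = G))
  }
  off <- pop$pedigree[!is.na(pop$pedigree$sire), ]
  blocks <- lapply(split(off$id, off$sire), function(ids) {
    M <- centered_dosage_cpp(pop$haps, as.integer(ids), markers, p)
    list(ids = as.integer(ids), G = crossprod(M) / denom)
  })
  .new_grm("sire_blocks", off$id, p, denom, blocks = blocks)
}

# Square relationship submatrix for a set of ids; block GRMs require all
# ids to fall inside one sire block.
.g_submatrix <- function(grm, ids) {
  ids <- as.integer(ids)
  if (grm$kind == "full") {
    idx <- match(ids, grm$ids)
    if (anyNA(idx)) stop("ids absent from the relationship matrix")
    return(grm$G[idx, idx, drop = FALSE])
  }
  for (b in grm$blocks) {
    idx <- match(ids, b$ids)
    if (!anyNA(idx)) return(b$G[idx, idx, drop = FALSE])
  }
  stop("ids span multiple sire-family blocks; build a full GRM")
}

#' Relationship distribution by kinship category
#'
#' Summarises off-diagonal realized relationships for offspring pairs:
#' full-sibs (same sire and dam), half-sibs (same sire, different dams)
#' and paternal half-sibs (same sire, dam possibly shared). When a group
#' assignment is given, within-group pairs of non-surplus groups form the
#' additional "genomic-close" category.
#'
#' @param grm A `grm` (full or sire-block).
#' @param pedigree Pedigree data.frame consistent with the GRM ids.
#' @param assignment Optional `group_assignment`.
#' @param return_pairs Attach the raw pooled pair values as attribute
#'   `"pairs"` (a list of numeric vectors per category).
#' @return data.frame with columns category, mean, sd, n_pairs; empty
#'   categories are absent.
#' @export
relationship_distribution <- function(grm, pedigree, assignment = NULL,
                                      return_pairs = FALSE) {
  off <- pedigree[!is.na(pedigree$sire), ]
  fs <- list(); hs <- list(); ps <- list()
  for (s in unique(off$sire)) {
    ids <- off$id[off$sire == s]
    if (length(ids) < 2) next
    B <- .g_submatrix(grm, ids)
    dam <- off$dam[match(ids, off$id)]
    iu <- upper.tri(B)
    same_dam <- outer(dam, dam, "==")[iu]
    vals <- B[iu]
    fs[[length(fs) + 1L]] <- vals[same_dam]
    hs[[length(hs) + 1L]] <- vals[!same_dam]
    ps[[length(ps) + 1L]] <- vals
  }
  pairs <- list(fullsib = unlist(fs), halfsib = unlist(hs),
                paternal_halfsib = unlist(ps))
  if (!is.null(assignment))
    pairs$genomic_close <- within_group_pairs(grm, assignment)
  pairs <- Filter(length, pairs)
  out <- data.frame(
    category = names(pairs),
    mean = vapply(pairs, mean, 0),
    sd = vapply(pairs, sd, 0),
    n_pairs = vapply(pairs, length, 0L),
    row.names = NULL)
  if (return_pairs) attr(out, "pairs") <- pairs
  out
}
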