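# GBLUP mixed models: REML variance components and GEBV prediction for
# individual records (y = 1 mu + Z g + e, e ~ N(0, I s2e)) and group
# records (y* = 1 mu + Z* g + e*, e* ~ N(0, R s2e), R = diag(group size)),
# with g ~ N(0, G s2g) in both.

#' Mixed-model specification
#'
#' Bundles a response, random-effect incidence, relationship matrix and
#' residual scaling into the model object consumed by [reml_fit()],
#' [restricted_loglik()] and [predict_gebv()]. The fixed part is an
#' intercept only.
#'
#' @param y Response vector (individual or group records).
#' @param Z Incidence matrix (records x animals; dense or sparse) linking
#'   records to the animals of `grm`.
#' @param grm A full `grm`.
#' @param R Diagonal of the residual scaling (default all 1).
#' @return Object of class `mm_spec`.
#' @export
mixed_model_spec <- function(y, Z, grm, R = rep(1, length(y))) {
  if (grm$kind != "full") stop("mixed models require a full GRM")
  Z <- methods::as(methods::as(Matrix::Matrix(Z, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(Z) == length(y), ncol(Z) == length(grm$ids),
            length(R) == length(y), all(R > 0))
  structure(list(y = as.numeric(y), Z = Z, grm = grm, R = as.numeric(R)),
            class = "mm_spec")
}

#' Individual-record GBLUP specification
#'
#' @param phenotypes Phenotype table (id, y).
#' @param grm A full `grm`.
#' @param ids Animals whose records enter the model (default: all
#'   phenotyped animals of the table).
#' @return An `mm_spec` with identity residual scaling.
#' @export
spec_individual <- function(phenotypes, grm,
                            ids = phenotypes$id[phenotypes$phenotyped]) {
  y <- phenotypes$y[match(ids, phenotypes$id)]
  if (anyNA(y)) stop("unphenotyped animals in `ids`")
  col <- match(ids, grm$ids)
  if (anyNA(col)) stop("animals absent from the GRM")
  Z <- Matrix::sparseMatrix(i = seq_along(ids), j = col, x = 1,
                            dims = c(length(ids), length(grm$ids)))
  mixed_model_spec(y, Z, grm)
}

#' Group-record GBLUP specification
#'
#' @param records A `group_records`.
#' @param grm A full `grm` whose ids match the record ids.
#' @return An `mm_spec` with residual scaling `diag(group size)`.
#' @export
spec_groups <- function(records, grm) {
  if (!identical(as.integer(records$ids), as.integer(grm$ids)))
    stop("group records were built against a different animal order")
  mixed_model_spec(records$y_star, records$Z_star, grm, records$R)
}

# One-off preparation shared by likelihood, REML and prediction: the
# kernel K = Z G Z', whitened by R^-1/2, and its eigendecomposition.
.mm_prepare <- function(spec) {
  ZG <- as.matrix(spec$Z %*% spec$grm$G)
  K <- as.matrix(ZG %*% Matrix::t(spec$Z))
  K <- (K + t(K)) / 2
  rs <- 1 / sqrt(spec$R)
  Kw <- K * tcrossprod(rs)
  ee <- eigen(Kw, symmetric = TRUE)
  d <- ee$values
  if (min(d) < -1e-6 * max(abs(d)))
    stop("kernel matrix is not positive semi-definite")
  d[d < 0] <- 0
  yw <- spec$y * rs
  xw <- rs  # X = 1 whitened
  list(ZG = ZG, rs = rs, d = d, U = ee$vectors,
       yt = drop(crossprod(ee$vectors, yw)),
       xt = drop(crossprod(ee$vectors, xw)),
       sumlogR = sum(log(spec$R)), n = length(spec$y))
}

.reml_ll_point <- function(prep, s2g, s2e) {
  a <- s2g * prep$d + s2e
  if (any(a <= 0)) return(-Inf)
  w <- 1 / a
  sxx <- sum(w * prep$xt^2)
  mu <- sum(w * prep$xt * prep$yt) / sxx
  r <- prep$yt - prep$xt * mu
  -0.5 * ((prep$n - 1) * log(2 * pi) + sum(log(a)) + prep$sumlogR +
            log(sxx) + sum(w * r^2))
}

#' Restricted log-likelihood of a GBLUP model
#'
#' Evaluates the REML log-likelihood (intercept profiled out by
#' generalized least squares) at given variance components, via one
#' eigendecomposition of the whitened kernel `R^-1/2 Z G Z' R^-1/2`.
#' Intended for small models and diagnostics; [reml_fit()] caches the
#' decomposition across evaluations.
#'
#' @param spec An `mm_spec`.
#' @param s2g Additive genetic variance.
#' @param s2e Residual variance.
#' @return Scalar restricted log-likelihood (including constants).
#' @export
restricted_loglik <- function(spec, s2g, s2e) {
  stopifnot(s2g >= 0, s2e >= 0, s2g + s2e > 0)
  .reml_ll_point(.mm_prepare(spec), s2g, s2e)
}

#' REML fit of a GBLUP model
#'
#' Profiles the residual variance and the intercept out of the restricted
#' likelihood and maximises over the log variance ratio
#' `log(s2g / s2e)` by golden-section/parabolic search on a bounded
#' interval, using a single eigendecomposition of the model kernel.
#' Estimates are non-negative by construction; a ratio estimate on the
#' search boundary is flagged as non-converged and the genetic variance
#' clamped at a small positive floor when the boundary is the lower one.
#'
#' @param spec An `mm_spec`.
#' @param bounds Search interval for `log(s2g / s2e)`.
#' @param tol Convergence tolerance of the 1-D search.
#' @return Object of class `reml_fit`: `s2g`, `s2e`, `ratio`, `loglik`,
#'   `converged`, `iterations`; the kernel decomposition is cached in
#'   attribute `"prep"` for [predict_gebv()].
#' @export
reml_fit <- function(spec, bounds = c(-8, 8), tol = 1e-8) {
  prep <- .mm_prepare(spec)
  n <- prep$n
  evals <- 0L
  obj <- function(t) {
    evals <<- evals + 1L
    delta <- exp(t)
    a <- delta * prep$d + 1
    w <- 1 / a
    sxx <- sum(w * prep$xt^2)
    mu <- sum(w * prep$xt * prep$yt) / sxx
    r <- prep$yt - prep$xt * mu
    s2e <- sum(w * r^2) / (n - 1)
    0.5 * ((n - 1) * (log(2 * pi) + log(s2e) + 1) + sum(log(a)) +
             prep$sumlogR + log(sxx))
  }
  opt <- optimize(obj, bounds, tol = tol)
  t_hat <- opt$minimum
  delta <- exp(t_hat)
  a <- delta * prep$d + 1
  w <- 1 / a
  sxx <- sum(w * prep$xt^2)
  mu <- sum(w * prep$xt * prep$yt) / sxx
  r <- prep$yt - prep$xt * mu
  s2e <- sum(w * r^2) / (n - 1)
  s2g <- delta * s2e
  interior <- (t_hat - bounds[1] > 1e-3) && (bounds[2] - t_hat > 1e-3)
  if (!interior && t_hat - bounds[1] <= 1e-3)
    s2g <- max(s2g, 1e-8 * stats::var(spec$y))
  out <- structure(list(s2g = s2g, s2e = s2e, ratio = delta,
                        loglik = .reml_ll_point(prep, s2g, s2e),
                        converged = interior, iterations = evals),
                   class = "reml_fit")
  attr(out, "prep") <- prep
  out
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> s2g = %.4f, s2e = %.4f, logLik = %.2f (%s, %d evals)\n",
              x$s2g, x$s2e, x$loglik,
              if (x$converged) "converged" else "boundary", x$iterations))
  invisible(x)
}

#' Predict genomic breeding values
#'
#' GEBV for every animal of the relationship matrix (including
#' unphenotyped parents and surplus offspring):
#' `g_hat = s2g G Z' V^-1 (y - 1 mu_hat)` with `mu_hat` the generalized
#' least-squares intercept, equivalent to the mixed-model-equation
#' solution at the given variances.
#'
#' @param spec An `mm_spec`.
#' @param variances A `reml_fit` (its cached decomposition is reused) or
#'   a list with elements `s2g` and `s2e`.
#' @return Object of class `gebv_result`: `mu` and named vector `gebv`.
#' @export
predict_gebv <- function(spec, variances) {
  prep <- attr(variances, "prep")
  if (is.null(prep)) prep <- .mm_prepare(spec)
  s2g <- variances$s2g; s2e <- variances$s2e
  stopifnot(is.numeric(s2g), is.numeric(s2e), s2e > 0, s2g >= 0)
  w <- 1 / (s2g * prep$d + s2e)
  sxx <- sum(w * prep$xt^2)
  mu <- sum(w * prep$xt * prep$yt) / sxx
  q <- prep$rs * drop(prep$U %*% (w * (prep$yt - prep$xt * mu)))
  gebv <- s2g * drop(crossprod(prep$ZG, q))
  names(gebv) <- spec$grm$ids
  structure(list(mu = mu, gebv = gebv), class = "gebv_result")
}

#' @export
print.gebv_result <- function(x, ...) {
  cat(sprintf("<gebv_result> mu = %.4f, %d animals, sd(gebv) = %.4f\n",
              x$mu, length(x$gebv), sd(x$gebv)))
  invisible(x)
}
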