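# GBLUP REML estimation and GEBV prediction.

# 20-record fixture with non-trivial grouping shared by several blocks.
gblup_fixture <- function(seed = 8) {
  set.seed(seed)
  tp <- toy_population(seed)
  asn <- group_random_fullsib(tp$pop$pedigree, 4)
  gr <- make_group_records(tp$phen, asn, ids = tp$grm$ids)
  list(tp = tp, asn = asn,
       spec_i = spec_individual(tp$phen, tp$grm),
       spec_g = spec_groups(gr, tp$grm))
}

test_that("restricted_loglik matches a naive determinant-based evaluation", {
  fx <- gblup_fixture()
  for (spec in list(fx$spec_i, fx$spec_g)) {
    Z <- as.matrix(spec$Z)
    K <- Z %*% spec$grm$G %*% t(Z)
    for (th in list(c(0.3, 0.7), c(1, 1), c(0.05, 1.5))) {
      expect_equal(restricted_loglik(spec, th[1], th[2]),
                   naive_reml_ll(spec$y, K, spec$R, th[1], th[2]),
                   tolerance = 1e-6)
    }
  }
})

test_that("REML optimum matches a dense grid-search oracle", {
  fx <- gblup_fixture()
  tp <- fx$tp
  spec <- spec_individual(tp$phen, tp$grm, ids = tp$pop$offspring[1:20])
  fit <- reml_fit(spec)
  Z <- as.matrix(spec$Z)
  K <- Z %*% spec$grm$G %*% t(Z)
  grid <- seq(0.01, 2, by = 0.005)
  best <- c(NA, NA, -Inf)
  for (s2g in grid) {
    ll <- vapply(grid, function(s2e)
      naive_reml_ll(spec$y, K, spec$R, s2g, s2e), 0)
    j <- which.max(ll)
    if (ll[j] > best[3]) best <- c(s2g, grid[j], ll[j])
  }
  # the fit dominates every grid point and sits at the grid optimum up to
  # the flatness of a 20-record likelihood surface
  expect_gte(fit$loglik, best[3] - 1e-6)
  expect_equal(fit$s2g, best[1], tolerance = 0.05)
  expect_equal(fit$s2e, best[2], tolerance = 0.05)
  expect_lt(abs(restricted_loglik(spec, best[1], best[2]) - fit$loglik),
            0.05)
})

test_that("group records of size one reproduce the individual model", {
  tp <- toy_population()
  asn <- group_random_fullsib(tp$pop$pedigree, 1)
  gr <- make_group_records(tp$phen, asn, ids = tp$grm$ids)
  spec_g <- spec_groups(gr, tp$grm)
  spec_i <- spec_individual(tp$phen, tp$grm,
                            ids = unlist(gr$members))
  for (th in list(c(0.3, 0.7), c(0.8, 0.2)))
    expect_equal(restricted_loglik(spec_g, th[1], th[2]),
                 restricted_loglik(spec_i, th[1], th[2]), tolerance = 1e-8)
  v <- list(s2g = 0.3, s2e = 0.7)
  gi <- predict_gebv(spec_i, v)
  gg <- predict_gebv(spec_g, v)
  expect_lt(max(abs(gi$gebv - gg$gebv)), 1e-8)
})

test_that("predict_gebv equals the closed-form mixed-model solution", {
  set.seed(13)
  A <- matrix(rnorm(25), 5, 5)
  G <- crossprod(A) / 5 + diag(5) * 0.1
  y <- rnorm(5, 0, 1)
  grm <- as_grm(G)
  # individual records
  spec <- mixed_model_spec(y, diag(5), grm)
  ref <- naive_blup(y, diag(5), G, rep(1, 5), 0.4, 0.6)
  got <- predict_gebv(spec, list(s2g = 0.4, s2e = 0.6))
  expect_equal(got$mu, ref$mu, tolerance = 1e-10)
  expect_equal(unname(got$gebv), ref$gebv, tolerance = 1e-10)
  # two groups of two plus an unphenotyped fifth animal
  Zs <- rbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 0))
  spec2 <- mixed_model_spec(c(sum(y[1:2]), sum(y[3:4])), Zs, grm,
                            R = c(2, 2))
  ref2 <- naive_blup(c(sum(y[1:2]), sum(y[3:4])), Zs, G, c(2, 2), 0.4, 0.6)
  got2 <- predict_gebv(spec2, list(s2g = 0.4, s2e = 0.6))
  expect_equal(unname(got2$gebv), ref2$gebv, tolerance = 1e-10)
})

test_that("REML estimates are scale-equivariant", {
  fx <- gblup_fixture()
  spec <- fx$spec_g
  fit1 <- reml_fit(spec)
  spec3 <- spec; spec3$y <- 3 * spec$y
  fit3 <- reml_fit(spec3)
  expect_equal(fit3$s2g, 9 * fit1$s2g, tolerance = 1e-4)
  expect_equal(fit3$s2e, 9 * fit1$s2e, tolerance = 1e-4)
})

test_that("vanishing genetic variance zeroes the GEBV", {
  fx <- gblup_fixture()
  got <- predict_gebv(fx$spec_i, list(s2g = 0, s2e = 0.7))
  expect_equal(unname(got$gebv), rep(0, length(got$gebv)))
  expect_equal(got$mu, mean(fx$spec_i$y), tolerance = 1e-8)
})

test_that("full-sibs in one group receive distinct GEBV under the group model", {
  fx <- gblup_fixture()
  fit <- reml_fit(fx$spec_g)
  pg <- predict_gebv(fx$spec_g, fit)
  asn <- fx$asn
  wg_var <- tapply(pg$gebv[as.character(asn$id)], asn$group, var)
  expect_true(all(wg_var > 0))
})
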