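# Group allocation: random pedigree-based partitions and supervised
# clustering on genomic relationships.

test_that("round_stop_threshold counts exchange possibilities", {
  expect_equal(round_stop_threshold(4, 4), 96L)
  expect_equal(round_stop_threshold(1, 2), 1L)
  expect_equal(round_stop_threshold(2, 8), 112L)
  expect_error(round_stop_threshold(4, 1), "n_g")
})

test_that("random full-sib grouping partitions families uniformly", {
  tp <- toy_population()
  ped <- tp$pop$pedigree
  asn <- group_random_fullsib(ped, 4)
  expect_equal(nrow(asn), 48)
  expect_true(all(table(asn$group) == 4))
  # group mates always share both parents
  off <- ped[!is.na(ped$sire), ]
  fam <- paste(off$sire, off$dam)[match(asn$id, off$id)]
  expect_true(all(tapply(fam, asn$group, function(x) length(unique(x))) == 1))
  expect_error(group_random_fullsib(ped, 3), "divisible")

  # partition census on one family of 8 into 2 groups of 4
  fam1 <- off[off$sire == off$sire[1] & off$dam == off$dam[1], ]
  ped1 <- ped[ped$id %in% c(fam1$id, fam1$sire[1], fam1$dam[1]), ]
  ids <- sort(fam1$id)
  set.seed(2)
  seen <- replicate(7000, {
    a <- group_random_fullsib(ped1, 4)
    g1 <- sort(a$id[a$group == a$group[a$id == ids[1]]])
    paste(match(g1, ids), collapse = ".")
  })
  tab <- table(seen)
  expect_equal(length(tab), 35L)  # all partitions reachable
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 1e-6)
})

test_that("paternal half-sib grouping keys on the sire only", {
  tp <- toy_population()
  asn <- group_random_paternal_halfsib(tp$pop$pedigree, 4)
  expect_true(all(table(asn$group) == 4))
  off <- tp$pop$pedigree[!is.na(tp$pop$pedigree$sire), ]
  sires <- off$sire[match(asn$id, off$id)]
  expect_true(all(tapply(sires, asn$group, function(x)
    length(unique(x))) == 1))
  expect_equal(length(unique(asn$group)), 3 * 4)
})

test_that("within-group objective equals pair enumeration", {
  set.seed(4)
  G <- crossprod(matrix(rnorm(256), 16, 16)) / 16
  gobj <- as_grm(G)
  ped <- data.frame(id = 1:16, sire = 100L, dam = 200L, sex = "F",
                    generation = 1L)
  asn <- group_random_fullsib(rbind(ped,
    data.frame(id = c(100L, 200L), sire = NA, dam = NA, sex = c("M", "F"),
               generation = 0L)), 4)
  # brute force over the 4 x choose(4,2) within-group pairs
  ref <- mean(unlist(lapply(split(asn$id, asn$group), function(ids) {
    out <- c()
    for (i in seq_along(ids)) for (k in seq_len(i - 1))
      out <- c(out, G[ids[i], ids[k]])
    out
  })))
  expect_equal(within_group_objective(gobj, asn), ref)
  expect_equal(within_group_objective(as_grm(diag(16)), asn), 0)
  Gc <- matrix(0.5, 16, 16); diag(Gc) <- 1
  expect_equal(within_group_objective(as_grm(Gc), asn), 0.5)
})

test_that("supervised clustering attains the exhaustive-partition optimum", {
  set.seed(10)
  for (draw in 1:50) {
    A <- matrix(rnorm(64), 8, 8)
    G <- (A + t(A)) / 2
    best_ref <- max(vapply(partitions_8_into_2(), partition_objective,
                           0, G = G))
    asn <- group_supervised(as_grm(G), 1:8, n_a = 4, n_g = 2, rounds = 60)
    expect_equal(attr(asn, "objective"), best_ref, tolerance = 1e-10)
    expect_equal(within_group_objective(as_grm(G), asn),
                 attr(asn, "objective"))
  }
})

test_that("supervised clustering beats or ties random grouping on its objective", {
  tp <- toy_population()
  asn <- group_supervised_all(tp$grm, tp$pop$pedigree, n_a = 2, n_g = 4,
                              rounds = 40)
  obj_sup <- within_group_objective(tp$grm, asn)
  set.seed(31)
  for (i in 1:5) {
    rnd <- group_random_fullsib(tp$pop$pedigree, 2)
    expect_gte(obj_sup, within_group_objective(tp$grm, rnd))
  }
  # flat landscape: any partition is optimal, objective equals the constant
  Gc <- matrix(0.3, 8, 8); diag(Gc) <- 1
  flat <- group_supervised(as_grm(Gc), 1:8, 4, 2, rounds = 5)
  expect_equal(attr(flat, "objective"), 0.3)
})

test_that("surplus animals keep group sizes exact and stay unscored", {
  set.seed(20)
  A <- matrix(rnorm(24 * 24), 24, 24)
  G <- (A + t(A)) / 2
  asn <- group_supervised(as_grm(G), 1:16, n_a = 4, n_g = 4, rounds = 30,
                          surplus_ids = 17:24)
  expect_equal(sum(!asn$surplus), 16)
  expect_equal(sum(asn$surplus), 8)
  expect_true(all(table(asn$group[!asn$surplus]) == 4))
  expect_true(all(is.na(asn$group[asn$surplus])))
  # widening the candidate pool cannot hurt the attainable objective
  no_sur <- group_supervised(as_grm(G[1:16, 1:16]), 1:16, 4, 4, rounds = 30)
  expect_gte(attr(asn, "objective") + 1e-10, attr(no_sur, "objective"))
})

test_that("supervised clustering is reproducible under a fixed seed", {
  tp <- toy_population()
  set.seed(77)
  a <- group_supervised_all(tp$grm, tp$pop$pedigree, 2, 4, rounds = 20)
  set.seed(77)
  b <- group_supervised_all(tp$grm, tp$pop$pedigree, 2, 4, rounds = 20)
  expect_identical(a, b)
})
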