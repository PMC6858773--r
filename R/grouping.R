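# Allocation of offspring into equal-size phenotyping groups: random
# pedigree-based rules and supervised clustering on genomic relationships.

.new_assignment <- function(df, n_a, method) {
  stopifnot(all(c("id", "family", "group", "surplus") %in% names(df)))
  structure(df, n_a = n_a, method = method,
            class = c("group_assignment", "data.frame"))
}

.random_partition <- function(pedigree, n_a, key, n_groups, method) {
  off <- pedigree[!is.na(pedigree$sire), ]
  fam <- if (key == "fullsib") paste(off$sire, off$dam, sep = ".")
         else as.character(off$sire)
  rows <- lapply(split(off$id, fam), function(ids) {
    f <- fam[match(ids[1], off$id)]
    if (is.null(n_groups)) {
      if (length(ids) %% n_a != 0)
        stop(sprintf("family %s has %d members, not divisible by group size %d",
                     f, length(ids), n_a))
      sel <- sample(ids)
      sur <- integer(0)
    } else {
      n_sel <- n_a * n_groups
      if (length(ids) < n_sel)
        stop(sprintf("family %s has %d members, fewer than %d needed",
                     f, length(ids), n_sel))
      sel <- sample(ids, n_sel)
      sur <- setdiff(ids, sel)
    }
    g <- rep(seq_len(length(sel) / n_a), each = n_a)
    rbind(data.frame(id = sel, family = f, group = paste(f, g, sep = "g"),
                     surplus = FALSE),
          if (length(sur)) data.frame(id = sur, family = f,
                                      group = NA_character_, surplus = TRUE))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  .new_assignment(df[order(df$id), ], n_a, method)
}

#' Random grouping of full-sibs
#'
#' Partitions every full-sib family uniformly at random into groups of
#' `n_a`. When `n_groups` is given, only `n_a * n_groups` randomly chosen
#' members per family are grouped and the rest form a surplus pool
#' (genotyped, unphenotyped).
#'
#' @param pedigree Pedigree data.frame (founders have NA sire/dam).
#' @param n_a Group size.
#' @param n_groups Optional number of groups per family.
#' @return A `group_assignment` data.frame: id, family, group, surplus.
#' @export
group_random_fullsib <- function(pedigree, n_a, n_groups = NULL)
  .random_partition(pedigree, n_a, "fullsib", n_groups, "random_fullsib")

#' Random grouping of paternal half-sibs
#'
#' As [group_random_fullsib()] but partitions each sire's offspring
#' (full- and half-sibs together) into groups of `n_a`.
#'
#' @inheritParams group_random_fullsib
#' @param n_groups Optional number of groups per sire family.
#' @return A `group_assignment`.
#' @export
group_random_paternal_halfsib <- function(pedigree, n_a, n_groups = NULL)
  .random_partition(pedigree, n_a, "halfsib", n_groups, "random_halfsib")

#' Stopping threshold of the supervised clustering round
#'
#' Number of consecutive non-improving exchange proposals after which a
#' clustering round terminates: `n_a^2 * sum(1:(n_g - 1))`, the number of
#' distinct ways of proposing an exchange of two animals between two
#' groups.
#'
#' @param n_a Animals per group.
#' @param n_g Groups per family.
#' @return Integer threshold.
#' @export
round_stop_threshold <- function(n_a, n_g) {
  stopifnot(n_a >= 1)
  if (n_g < 2) stop("n_g must be at least 2")
  as.integer(n_a^2 * n_g * (n_g - 1) / 2)
}

#' Pooled mean within-group relationship
#'
#' Mean of the relationship coefficients over all unordered within-group
#' pairs, pooled across all non-surplus groups. With equal group sizes
#' this equals the mean of per-group means.
#'
#' @param grm A `grm`.
#' @param assignment A `group_assignment`.
#' @return Scalar objective value.
#' @export
within_group_objective <- function(grm, assignment) {
  v <- within_group_pairs(grm, assignment)
  if (!length(v)) stop("no within-group pairs: all groups have size 1?")
  mean(v)
}

#' Within-group pair relationship values
#'
#' Raw relationship coefficients of all unordered pairs of group mates
#' (surplus pool excluded), used for pooling distributions across
#' replicates.
#'
#' @inheritParams within_group_objective
#' @return Numeric vector, one entry per within-group pair.
#' @export
within_group_pairs <- function(grm, assignment) {
  grouped <- assignment[!assignment$surplus, , drop = FALSE]
  unlist(lapply(split(grouped$id, grouped$group), function(ids) {
    if (length(ids) < 2) return(numeric(0))
    B <- .g_submatrix(grm, ids)
    B[upper.tri(B)]
  }), use.names = FALSE)
}

#' Supervised clustering of one family into groups
#'
#' Evolutionary (stochastic swap) algorithm that maximises the mean
#' genomic relationship between group members. Each round starts from a
#' random assignment of the family into `n_g` groups of `n_a`; exchanges
#' of two randomly chosen animals between two randomly chosen groups are
#' accepted only when they strictly increase the within-group mean; a
#' round ends after [round_stop_threshold()] consecutive non-improving
#' proposals, with failed pairs excluded from re-proposal until the group
#' composition changes. The best assignment over `rounds` independent
#' rounds is returned.
#'
#' With `surplus_ids`, an extra unscored pool holds the surplus animals:
#' it takes part in exchanges (groups are sampled with probability
#' proportional to their size) but not in the objective, so group members
#' can be traded against surplus animals while sizes stay exact.
#'
#' @param grm A `grm` covering all ids.
#' @param ids Ids of the `n_a * n_g` animals to allocate.
#' @param n_a Group size.
#' @param n_g Number of scored groups.
#' @param rounds Number of independent restarts (default 300).
#' @param surplus_ids Optional ids of surplus (unphenotyped) animals.
#' @param family Family label used in group names.
#' @return A `group_assignment` with attribute `objective`, the pooled
#'   within-group mean of the returned assignment.
#' @export
group_supervised <- function(grm, ids, n_a, n_g, rounds = 300L,
                             surplus_ids = NULL, family = "f") {
  n_a <- as.integer(n_a); n_g <- as.integer(n_g)
  if (length(ids) != n_a * n_g)
    stop(sprintf("got %d ids for %d groups of %d", length(ids), n_g, n_a))
  all_ids <- c(ids, surplus_ids)
  B <- .g_submatrix(grm, all_ids)
  res <- supervised_cluster_cpp(B, n_a, n_g, length(surplus_ids),
                                as.integer(rounds),
                                round_stop_threshold(n_a, n_g))
  grp <- res$group
  df <- data.frame(
    id = all_ids,
    family = family,
    group = ifelse(grp == 0L, NA_character_,
                   paste(family, grp, sep = "g")),
    surplus = grp == 0L)
  out <- .new_assignment(df[order(df$id), ], n_a, "supervised")
  attr(out, "objective") <- res$objective
  out
}

#' Supervised clustering applied per full-sib family
#'
#' Runs [group_supervised()] independently for every full-sib family of a
#' pedigree; with `n_surplus > 0` each family contributes that many
#' surplus animals, the algorithm choosing which. Set
#' `per_family = FALSE` to cluster the whole offspring population in one
#' call (much slower; group members then still end up being full-sibs in
#' nested designs because cross-family relationships are far lower).
#'
#' @param grm A `grm` (sire-block GRMs suffice for per-family mode).
#' @param pedigree Pedigree data.frame.
#' @param n_a Group size.
#' @param n_g Groups per family.
#' @param rounds Restarts per family.
#' @param n_surplus Surplus animals per family.
#' @param per_family Cluster within full-sib families (default) or over
#'   the whole offspring set at once.
#' @return A `group_assignment` covering all offspring.
#' @export
group_supervised_all <- function(grm, pedigree, n_a, n_g, rounds = 300L,
                                 n_surplus = 0L, per_family = TRUE) {
  off <- pedigree[!is.na(pedigree$sire), ]
  fam <- paste(off$sire, off$dam, sep = ".")
  if (!per_family) {
    n_tot <- nrow(off)
    if (n_surplus > 0) stop("surplus pool requires per-family mode")
    if (n_tot %% n_a != 0) stop("offspring count not divisible by group size")
    return(group_supervised(grm, off$id, n_a, n_tot %/% n_a, rounds,
                            family = "all"))
  }
  parts <- lapply(split(off$id, fam), function(ids) {
    f <- fam[match(ids[1], off$id)]
    if (length(ids) != n_a * n_g + n_surplus)
      stop(sprintf("family %s has %d members; expected %d grouped + %d surplus",
                   f, length(ids), n_a * n_g, n_surplus))
    a <- group_supervised(grm, ids[seq_len(n_a * n_g)], n_a, n_g, rounds,
                          surplus_ids = if (n_surplus > 0)
                            ids[n_a * n_g + seq_len(n_surplus)],
                          family = f)
    a
  })
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  .new_assignment(df[order(df$id), ], n_a, "supervised")
}
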