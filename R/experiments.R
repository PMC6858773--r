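# Scenario presets, replicate orchestration and aggregation.

#' Scenario configuration
#'
#' Presets reproduce the study conditions of the base breeding scheme and
#' the four sensitivity settings: surplus genotyped offspring
#' (`ss1_16`, `ss1_32`), groups per family (`ss2_g2`, `ss2_g8`), family
#' size (`ss3_f8`, `ss3_f32`, `ss3_f48`) and genome size (`ss4`). The
#' base scenario is a 916 cM, 26-chromosome genome with 2,000 QTL and
#' 40,000 markers, a 20-sire x 10-dam x 16-offspring nested design,
#' `s2a = 0.3`, `s2e = 0.7`, and 4 groups of 4 per full-sib family.
#'
#' @param name Scenario name (see above).
#' @param ... Named overrides of any config field (`genome`, `history`,
#'   `design`, `n_a`, `n_g`, `n_surplus`, `n_top_males`, `n_top_females`,
#'   `var_a`, `var_e`, `rounds`, `methods`).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(name = c("base", "ss1_16", "ss1_32", "ss2_g2",
                                     "ss2_g8", "ss3_f8", "ss3_f32",
                                     "ss3_f48", "ss4"), ...) {
  name <- match.arg(name)
  cfg <- list(
    name = name,
    genome = genome_config(),
    history = historical_config(),
    design = list(n_sires = 20L, dams_per_sire = 10L,
                  offspring_per_dam = 16L),
    n_a = 4L, n_g = 4L, n_surplus = 0L,
    n_top_males = 20L, n_top_females = 200L,
    var_a = 0.3, var_e = 0.7, rounds = 300L,
    methods = c("individual", "supervised", "random_fullsib",
                "random_halfsib"))
  mod <- switch(name,
    base = list(),
    ss1_16 = list(design = list(n_sires = 20L, dams_per_sire = 10L,
                                offspring_per_dam = 32L), n_surplus = 16L),
    ss1_32 = list(design = list(n_sires = 20L, dams_per_sire = 10L,
                                offspring_per_dam = 48L), n_surplus = 32L),
    ss2_g2 = list(n_a = 8L, n_g = 2L),
    ss2_g8 = list(n_a = 2L, n_g = 8L),
    ss3_f8 = list(design = list(n_sires = 20L, dams_per_sire = 10L,
                                offspring_per_dam = 8L), n_a = 2L),
    ss3_f32 = list(design = list(n_sires = 20L, dams_per_sire = 10L,
                                 offspring_per_dam = 32L), n_a = 8L),
    ss3_f48 = list(design = list(n_sires = 20L, dams_per_sire = 10L,
                                 offspring_per_dam = 48L), n_a = 12L),
    ss4 = list(genome = genome_config(n_chr = 30L, total_cM = 3000)))
  cfg[names(mod)] <- mod
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (cfg$design$offspring_per_dam != cfg$n_a * cfg$n_g + cfg$n_surplus)
    stop("offspring_per_dam must equal n_a * n_g + n_surplus")
  structure(cfg, class = "scenario_config")
}

# Deterministic per-replicate child seed, kept within 32-bit range.
.child_seed <- function(seed, replicate)
  as.integer((as.numeric(seed) * 48271 + as.numeric(replicate) * 7919) %%
               2147483647)

#' Run one simulation replicate
#'
#' Executes the pipeline: base population, trait, nested mating,
#' phenotypes, GRM, grouping per method, group records, REML and GEBV,
#' and evaluation metrics. With `fit = FALSE` only the relationship
#' summaries are produced, from per-sire-family GRM blocks, skipping the
#' full matrix and all model fits (sufficient for relationship targets
#' and much cheaper).
#'
#' @param config A `scenario_config`.
#' @param replicate Replicate index (seeds the run together with `seed`).
#' @param seed Master seed.
#' @param fit Fit the GBLUP models (default TRUE).
#' @param methods Subset of the config's methods to run.
#' @return Object of class `replicate_result`: `metrics` (one row per
#'   method: s2g, s2e, converged, accuracy, bias, coancestry),
#'   `category_pairs`, `within_pairs` (per grouping method),
#'   `objectives`, and `counts`.
#' @export
run_replicate <- function(config, replicate = 1L, seed = 1L, fit = TRUE,
                          methods = config$methods) {
  set.seed(.child_seed(seed, replicate))
  des <- config$design
  n_parents <- des$n_sires + des$n_sires * des$dams_per_sire
  founders <- simulate_base_population(config$genome, config$history,
                                       n_founders = n_parents)
  trait <- assign_qtl_effects(founders, config$var_a, config$var_e)
  pop <- nested_mating(founders, des)
  phen <- simulate_phenotypes(pop, trait, phenotyped_ids = pop$offspring)
  tbv <- phen$tbv; names(tbv) <- phen$id
  grm <- grm_from_population(pop, mode = if (fit) "full" else "sire_blocks")
  cats <- relationship_distribution(grm, pop$pedigree, return_pairs = TRUE)
  ped <- pop$pedigree
  n_grouped <- config$n_a * config$n_g

  metrics <- list(); within <- list(); objectives <- list()
  n_groups <- list()
  eval_arm <- function(method, spec, ids_ph) {
    f <- reml_fit(spec)
    pg <- predict_gebv(spec, f)
    data.frame(method = method,
               record_type = if (method == "individual") "individual"
                             else "group",
               s2g = f$s2g, s2e = f$s2e, converged = f$converged,
               accuracy = accuracy(pg, tbv, ids_ph),
               bias = bias_regression(pg, tbv, ids_ph),
               coancestry = coancestry_top(grm, pg, ped, ids_ph,
                                           config$n_top_males,
                                           config$n_top_females))
  }
  for (m in methods) {
    if (m == "individual") {
      if (!fit) next
      ids_ph <- if (config$n_surplus > 0) {
        off <- ped[!is.na(ped$sire), ]
        fam <- paste(off$sire, off$dam, sep = ".")
        sort(unlist(lapply(split(off$id, fam), sample, size = n_grouped)))
      } else pop$offspring
      metrics[[m]] <- eval_arm(m, spec_individual(phen, grm, ids_ph), ids_ph)
      next
    }
    asn <- switch(m,
      supervised = group_supervised_all(grm, ped, config$n_a, config$n_g,
                                        config$rounds, config$n_surplus),
      random_fullsib = group_random_fullsib(
        ped, config$n_a,
        n_groups = if (config$n_surplus > 0) config$n_g),
      random_halfsib = group_random_paternal_halfsib(
        ped, config$n_a,
        n_groups = if (config$n_surplus > 0)
          config$n_g * des$dams_per_sire),
      stop(sprintf("unknown method '%s'", m)))
    within[[m]] <- within_group_pairs(grm, asn)
    objectives[[m]] <- mean(within[[m]])
    n_groups[[m]] <- length(unique(asn$group[!asn$surplus]))
    if (fit) {
      gr <- make_group_records(phen, asn, ids = grm$ids)
      ids_ph <- sort(asn$id[!asn$surplus])
      metrics[[m]] <- eval_arm(m, spec_groups(gr, grm), ids_ph)
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  if (!is.null(metrics)) rownames(metrics) <- NULL
  structure(list(scenario = config$name, replicate = replicate,
                 metrics = metrics,
                 category_pairs = attr(cats, "pairs"),
                 within_pairs = within, objectives = objectives,
                 counts = list(n_animals = length(pop$ids),
                               n_offspring = length(pop$offspring),
                               n_groups = n_groups)),
            class = "replicate_result")
}

#' Run a scenario over replicates and aggregate
#'
#' Replicates are seeded independently and deterministically from the
#' master seed, so results do not depend on execution order. Metric means
#' and SDs are taken over replicates; relationship distributions are
#' pooled over all pairs from all replicates.
#'
#' @param config A `scenario_config`.
#' @param n_replicates Number of replicates.
#' @param seed Master seed.
#' @param fit Fit GBLUP models (see [run_replicate()]).
#' @param methods Methods to run.
#' @param verbose Print per-replicate progress.
#' @return Object of class `scenario_aggregate`: `metrics` (mean and sd
#'   per method and metric), `relationships` (pooled per category),
#'   `within_group` (pooled per grouping method), `replicates` (list of
#'   `replicate_result`), `config`.
#' @export
run_scenario <- function(config, n_replicates = 10L, seed = 1L, fit = TRUE,
                         methods = config$methods, verbose = FALSE) {
  stopifnot(n_replicates >= 1)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reps[[r]] <- run_replicate(config, r, seed, fit = fit, methods = methods)
    if (verbose)
      message(sprintf("[%s] replicate %d/%d done", config$name, r,
                      n_replicates))
  }
  pool <- function(field) {
    keys <- unique(unlist(lapply(reps, function(x) names(x[[field]]))))
    out <- lapply(keys, function(k)
      unlist(lapply(reps, function(x) x[[field]][[k]]), use.names = FALSE))
    names(out) <- keys
    out
  }
  cat_pool <- pool("category_pairs")
  win_pool <- pool("within_pairs")
  summarise <- function(lst) data.frame(
    category = names(lst),
    mean = vapply(lst, mean, 0),
    sd = vapply(lst, function(v) if (length(v) > 1) sd(v) else NA_real_, 0),
    n_pairs = vapply(lst, length, 0L), row.names = NULL)
  metrics <- NULL
  if (fit) {
    all_m <- do.call(rbind, lapply(seq_along(reps), function(r)
      cbind(replicate = r, reps[[r]]$metrics)))
    num <- c("s2g", "s2e", "accuracy", "bias", "coancestry")
    agg <- lapply(split(all_m, all_m$method), function(d) {
      means <- vapply(num, function(v) mean(d[[v]]), 0)
      sds <- vapply(num, function(v)
        if (nrow(d) > 1) sd(d[[v]]) else NA_real_, 0)
      data.frame(method = d$method[1], metric = num, mean = means,
                 sd = sds, row.names = NULL)
    })
    metrics <- do.call(rbind, agg)
    rownames(metrics) <- NULL
  }
  structure(list(scenario = config$name, n_replicates = n_replicates,
                 metrics = metrics,
                 relationships = summarise(cat_pool),
                 within_group = summarise(win_pool),
                 replicates = reps, config = config),
            class = "scenario_aggregate")
}

#' @export
print.scenario_aggregate <- function(x, ...) {
  cat(sprintf("<scenario_aggregate> %s, %d replicates\n", x$scenario,
              x$n_replicates))
  if (!is.null(x$metrics)) { cat("metrics (mean over replicates):\n")
    print(x$metrics, digits = 3) }
  cat("pooled relationships:\n"); print(x$relationships, digits = 3)
  cat("pooled within-group:\n"); print(x$within_group, digits = 3)
  invisible(x)
}

#' Relative accuracy gain between methods
#'
#' `100 * (acc_a - acc_b) / acc_b` on replicate-mean accuracies.
#'
#' @param aggregate A `scenario_aggregate` with fitted metrics.
#' @param method_a,method_b Method names.
#' @return Percent gain of `method_a` over `method_b`.
#' @export
relative_accuracy_gain <- function(aggregate, method_a, method_b) {
  m <- aggregate$metrics
  if (is.null(m)) stop("aggregate has no fitted metrics")
  get <- function(me) {
    v <- m$mean[m$method == me & m$metric == "accuracy"]
    if (!length(v)) stop(sprintf("method '%s' absent", me))
    v
  }
  a <- get(method_a); b <- get(method_b)
  if (b == 0) stop("reference accuracy is zero")
  100 * (a - b) / b
}
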