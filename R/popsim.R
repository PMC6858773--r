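# Population simulation: genome map, drift-phase founders, nested mating,
# QTL trait architecture and phenotypes.

#' Genome configuration
#'
#' Describes the simulated genome: number of chromosomes, map lengths and
#' locus counts. The default is 26 chromosomes totalling 916 cM carrying
#' 2,000 QTL and 40,000 neutral markers; the long-genome sensitivity
#' setting uses 30 chromosomes of 100 cM each.
#'
#' @param n_chr Number of chromosomes.
#' @param total_cM Total map length in centiMorgans; split equally over
#'   chromosomes unless `chr_cM` is given.
#' @param chr_cM Optional vector of per-chromosome lengths (cM).
#' @param n_qtl,n_marker Number of QTL and neutral marker loci to retain.
#' @param maf_min Minimum minor allele frequency a locus must have in the
#'   founder sample to be retained.
#' @return An object of class `genome_config`.
#' @export
genome_config <- function(n_chr = 26L, total_cM = 916, chr_cM = NULL,
                          n_qtl = 2000L, n_marker = 40000L,
                          maf_min = 0.05) {
  n_chr <- as.integer(n_chr)
  if (is.null(chr_cM)) chr_cM <- rep(total_cM / n_chr, n_chr)
  stopifnot(length(chr_cM) == n_chr, all(chr_cM >= 0),
            n_qtl >= 0, n_marker >= 1, maf_min >= 0, maf_min < 0.5)
  structure(list(n_chr = n_chr, chr_cM = as.numeric(chr_cM),
                 n_qtl = as.integer(n_qtl), n_marker = as.integer(n_marker),
                 maf_min = maf_min),
            class = "genome_config")
}

#' Historical (drift-phase) population configuration
#'
#' Parameters of the forward Wright--Fisher phase that shapes founder
#' allele frequencies and linkage disequilibrium: a random-mating
#' population of `n_ind` diploids is simulated for `generations` discrete
#' generations, starting from candidate loci at frequency 0.5 with
#' recombination active. `oversample` controls how many candidate loci are
#' simulated per retained locus, to allow for losses to the MAF filter.
#'
#' @param n_ind Diploid population size of the drift phase.
#' @param generations Number of discrete generations.
#' @param oversample Candidate-locus oversampling factor (> 1).
#' @return An object of class `historical_config`.
#' @export
historical_config <- function(n_ind = 100L, generations = 100L,
                              oversample = 2) {
  stopifnot(n_ind >= 2, generations >= 0, oversample >= 1)
  structure(list(n_ind = as.integer(n_ind),
                 generations = as.integer(generations),
                 oversample = oversample),
            class = "historical_config")
}

# 0-based per-chromosome locus index ranges for the C++ kernels.
.map_ranges <- function(map) {
  n_chr <- length(map$chr_cM)
  first <- integer(n_chr); last <- integer(n_chr)
  for (c in seq_len(n_chr)) {
    idx <- which(map$chr == c)
    if (length(idx)) {
      first[c] <- idx[1] - 1L
      last[c] <- idx[length(idx)] - 1L
    } else {
      first[c] <- 0L; last[c] <- -1L
    }
  }
  list(first = first, last = last)
}

.new_map <- function(chr_cM, chr, pos, role) {
  o <- order(chr, pos)
  structure(list(chr_cM = chr_cM, chr = as.integer(chr[o]),
                 pos = as.numeric(pos[o]), role = role[o]),
            class = "genome_map")
}

#' Simulate the base (founder) population
#'
#' Places candidate loci uniformly at random along the genome, runs the
#' drift phase, samples `n_founders` individuals, and retains the
#' configured numbers of QTL and marker loci among candidates whose minor
#' allele frequency in the founder sample is at least `genome$maf_min`.
#' QTL and marker roles are assigned at random among the retained loci, so
#' both are interleaved along the genome.
#'
#' @param genome A [genome_config()].
#' @param history A [historical_config()].
#' @param n_founders Number of founder individuals to sample.
#' @return An object of class `founder_pop`: list with elements `map`
#'   (class `genome_map`: `chr_cM`, `chr`, `pos`, `role`), `haps` (raw
#'   matrix, loci x 2*n_founders) and `ids`.
#' @export
simulate_base_population <- function(genome = genome_config(),
                                     history = historical_config(),
                                     n_founders = 220L) {
  n_target <- genome$n_qtl + genome$n_marker
  n_cand <- as.integer(ceiling(history$oversample * n_target))
  w <- if (sum(genome$chr_cM) > 0) genome$chr_cM / sum(genome$chr_cM)
       else rep(1 / genome$n_chr, genome$n_chr)
  chr <- sample.int(genome$n_chr, n_cand, replace = TRUE, prob = w)
  pos <- runif(n_cand, 0, genome$chr_cM[chr])
  cand_map <- .new_map(genome$chr_cM, chr, pos, rep("cand", n_cand))
  rg <- .map_ranges(cand_map)
  haps <- drift_phase_cpp(history$n_ind, history$generations,
                          as.integer(n_founders),
                          cand_map$pos, rg$first, rg$last, cand_map$chr_cM)
  p <- freq_cpp(haps, seq_len(n_cand))
  keep <- which(pmin(p, 1 - p) >= genome$maf_min)
  if (length(keep) < n_target)
    stop(sprintf(paste0(
      "only %d of %d candidate loci reached MAF >= %.3g in the founder ",
      "sample; increase the oversample factor of historical_config()"),
      length(keep), n_cand, genome$maf_min))
  sel <- sort(sample(keep, n_target))
  role <- rep("marker", n_target)
  role[sample.int(n_target, genome$n_qtl)] <- "qtl"
  map <- structure(list(chr_cM = genome$chr_cM, chr = cand_map$chr[sel],
                        pos = cand_map$pos[sel], role = role),
                   class = "genome_map")
  structure(list(map = map, haps = haps[sel, , drop = FALSE],
                 ids = seq_len(n_founders)),
            class = "founder_pop")
}

#' Draw recombinant gametes from one individual
#'
#' Meiosis under the Haldane model: per chromosome the number of
#' crossovers is Poisson(map length in Morgans), crossover positions are
#' uniform and there is no interference; chromosomes segregate
#' independently.
#'
#' @param pop A `founder_pop` or `population` object.
#' @param id Individual id (index into `pop$ids`).
#' @param n Number of gametes to draw.
#' @return Integer matrix of alleles, loci in rows, one column per gamete.
#' @export
make_gamete <- function(pop, id, n = 1L) {
  stopifnot(id %in% pop$ids)
  rg <- .map_ranges(pop$map)
  out <- gametes_cpp(pop$haps, rep(as.integer(id), n),
                     pop$map$pos, rg$first, rg$last, pop$map$chr_cM)
  matrix(as.integer(out), nrow = nrow(out))
}

#' Nested mating design
#'
#' Samples sires and dams without replacement from the founders and
#' produces the offspring generation: every sire is mated to
#' `dams_per_sire` dams and every dam produces `offspring_per_dam`
#' full-sib offspring, each built from one recombinant gamete per parent.
#' Offspring sex is assigned at random with a 1:1 ratio.
#'
#' @param founders A `founder_pop` from [simulate_base_population()].
#' @param design List with `n_sires`, `dams_per_sire`, `offspring_per_dam`.
#' @return An object of class `population`: `map`, `haps` (founders
#'   followed by offspring), `pedigree` (data.frame with id, sire, dam,
#'   sex, generation), `ids`, and `offspring` (ids of generation 1).
#' @export
nested_mating <- function(founders,
                          design = list(n_sires = 20L, dams_per_sire = 10L,
                                        offspring_per_dam = 16L)) {
  n_s <- as.integer(design$n_sires)
  n_d <- n_s * as.integer(design$dams_per_sire)
  n_per_dam <- as.integer(design$offspring_per_dam)
  n_f <- length(founders$ids)
  if (n_f < n_s + n_d)
    stop(sprintf("design needs %d founders (%d sires + %d dams) but only %d available",
                 n_s + n_d, n_s, n_d, n_f))
  roles <- sample(founders$ids)
  sires <- sort(roles[seq_len(n_s)])
  dams <- sort(roles[n_s + seq_len(n_d)])
  sex_f <- rep(NA_character_, n_f)
  sex_f[sires] <- "M"; sex_f[dams] <- "F"
  if (anyNA(sex_f)) sex_f[is.na(sex_f)] <- sample(c("M", "F"),
                                                  sum(is.na(sex_f)), TRUE)
  n_off <- n_d * n_per_dam
  off_ids <- n_f + seq_len(n_off)
  off_sire <- rep(sires, each = design$dams_per_sire * n_per_dam)
  off_dam <- rep(dams, each = n_per_dam)
  rg <- .map_ranges(founders$map)
  sg <- gametes_cpp(founders$haps, off_sire, founders$map$pos,
                    rg$first, rg$last, founders$map$chr_cM)
  dg <- gametes_cpp(founders$haps, off_dam, founders$map$pos,
                    rg$first, rg$last, founders$map$chr_cM)
  L <- nrow(founders$haps)
  off_haps <- matrix(raw(1), L, 2L * n_off)
  off_haps[, seq(1L, 2L * n_off, by = 2L)] <- sg
  off_haps[, seq(2L, 2L * n_off, by = 2L)] <- dg
  ped <- data.frame(
    id = c(founders$ids, off_ids),
    sire = c(rep(NA_integer_, n_f), off_sire),
    dam = c(rep(NA_integer_, n_f), off_dam),
    sex = c(sex_f, sample(c("M", "F"), n_off, TRUE)),
    generation = c(rep(0L, n_f), rep(1L, n_off)))
  structure(list(map = founders$map, haps = cbind(founders$haps, off_haps),
                 pedigree = ped, ids = ped$id, offspring = off_ids),
            class = "population")
}

#' Assign QTL allele-substitution effects
#'
#' Effects are drawn i.i.d. from N(0, 1) and rescaled by a single scalar
#' so that the empirical variance of true breeding values across the
#' founders equals `target_va` exactly. TBVs are subsequently reported as
#' deviations from the founder mean, so the trait mean is 0.
#'
#' @param founders A `founder_pop`.
#' @param target_va Target additive genetic variance (default 0.3).
#' @param var_e Residual variance used later for phenotypes (default 0.7).
#' @return Object of class `trait_arch`: `qtl` (locus indices), `effects`,
#'   `var_a`, `var_e`, `mu`, `founder_mean`.
#' @export
assign_qtl_effects <- function(founders, target_va = 0.3, var_e = 0.7) {
  qtl <- which(founders$map$role == "qtl")
  if (!length(qtl)) stop("genome map has no QTL loci")
  alpha <- rnorm(length(qtl))
  D <- centered_dosage_cpp(founders$haps, seq_along(founders$ids),
                           qtl, numeric(length(qtl)))
  g <- drop(crossprod(D, alpha))
  v <- var(g)
  if (!is.finite(v) || v <= 0)
    stop("founder TBV variance is zero before rescaling; all QTL fixed?")
  alpha <- alpha * sqrt(target_va / v)
  structure(list(qtl = qtl, effects = alpha, var_a = target_va,
                 var_e = var_e, mu = 0,
                 founder_mean = mean(g) * sqrt(target_va / v)),
            class = "trait_arch")
}

#' True breeding values
#'
#' Sum of QTL dosages weighted by allele-substitution effects, expressed
#' as a deviation from the founder mean.
#'
#' @param pop A `population` (or `founder_pop`).
#' @param trait A `trait_arch` from [assign_qtl_effects()].
#' @param ids Animal ids (default: all).
#' @return Named numeric vector of TBVs.
#' @export
true_breeding_values <- function(pop, trait, ids = pop$ids) {
  D <- centered_dosage_cpp(pop$haps, as.integer(ids), trait$qtl,
                           numeric(length(trait$qtl)))
  tbv <- drop(crossprod(D, trait$effects)) - trait$founder_mean
  names(tbv) <- ids
  tbv
}

#' Simulate phenotypes
#'
#' `y_i = mu + tbv_i + e_i` with residuals drawn independently from
#' N(0, var_e); only animals in `phenotyped_ids` receive residuals and
#' phenotypes, all animals get a TBV.
#'
#' @param pop A `population`.
#' @param trait A `trait_arch`.
#' @param phenotyped_ids Ids of animals that are phenotyped (default: the
#'   offspring generation).
#' @return data.frame with columns id, tbv, e, y, phenotyped.
#' @export
simulate_phenotypes <- function(pop, trait, phenotyped_ids = pop$offspring) {
  tbv <- true_breeding_values(pop, trait)
  n <- length(pop$ids)
  e <- rep(NA_real_, n); y <- rep(NA_real_, n)
  ph <- pop$ids %in% phenotyped_ids
  e[ph] <- rnorm(sum(ph), 0, sqrt(trait$var_e))
  y[ph] <- trait$mu + tbv[ph] + e[ph]
  data.frame(id = pop$ids, tbv = unname(tbv), e = e, y = y,
             phenotyped = ph)
}
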