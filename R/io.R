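# Plain-text interchange: PLINK-raw-style dosage tables, pedigree CSV,
# group assignments and GRM export. These allow the grouping and
# evaluation machinery to run standalone on user data.

#' Extract a dosage matrix from a simulated population
#'
#' @param pop A `population` or `founder_pop`.
#' @param which `"marker"` (default), `"qtl"` or `"all"` loci.
#' @param ids Animals (default all).
#' @return Integer matrix, animals x loci, dosages 0/1/2; row names are
#'   animal ids, column names `chr<chr>_<pos>`.
#' @export
dosage_matrix <- function(pop, which = c("marker", "qtl", "all"),
                          ids = pop$ids) {
  which <- match.arg(which)
  loci <- if (which == "all") seq_along(pop$map$chr)
          else which(pop$map$role == which)
  D <- dosage_int_cpp(pop$haps, as.integer(ids), loci)
  dimnames(D) <- list(ids, sprintf("chr%d_%0.4f", pop$map$chr[loci],
                                   pop$map$pos[loci]))
  D
}

#' Write a PLINK-raw-style dosage table
#'
#' Whitespace-delimited table with header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per marker
#' (counted-allele dosages 0/1/2).
#'
#' @param dosages Integer matrix, animals x markers, with animal ids as
#'   row names.
#' @param file Output path.
#' @param pedigree Optional pedigree supplying PAT/MAT/SEX.
#' @export
write_dosage_raw <- function(dosages, file, pedigree = NULL) {
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- seq_len(nrow(dosages))
  pat <- mat <- rep(0L, nrow(dosages)); sex <- rep(0L, nrow(dosages))
  if (!is.null(pedigree)) {
    i <- match(as.integer(ids), pedigree$id)
    pat <- ifelse(is.na(pedigree$sire[i]), 0L, pedigree$sire[i])
    mat <- ifelse(is.na(pedigree$dam[i]), 0L, pedigree$dam[i])
    sex <- ifelse(pedigree$sex[i] == "M", 1L, 2L)
  }
  df <- data.frame(FID = ids, IID = ids, PAT = pat, MAT = mat, SEX = sex,
                   PHENOTYPE = -9L, dosages, check.names = FALSE)
  write.table(df, file, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a PLINK-raw-style dosage table
#'
#' @param file Path written by [write_dosage_raw()] or `plink --recode A`.
#' @return Integer dosage matrix with animal ids (IID) as row names.
#' @export
read_dosage_raw <- function(file) {
  df <- read.table(file, header = TRUE, check.names = FALSE)
  D <- as.matrix(df[, -(1:6), drop = FALSE])
  storage.mode(D) <- "integer"
  rownames(D) <- df$IID
  D
}

#' Write / read a pedigree CSV
#'
#' Columns `id,sire,dam,sex,generation`; founders have empty sire/dam and
#' generation 0.
#'
#' @param pedigree Pedigree data.frame.
#' @param file Path.
#' @export
write_pedigree <- function(pedigree, file) {
  write.csv(pedigree, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(file) {
  ped <- read.csv(file, na.strings = c("", "NA"))
  ped$sex <- as.character(ped$sex)
  ped
}

#' Write / read a group assignment CSV
#'
#' Columns `animal_id,family_id,group_id,is_surplus`.
#'
#' @param assignment A `group_assignment`.
#' @param file Path.
#' @export
write_group_assignment <- function(assignment, file) {
  df <- data.frame(animal_id = assignment$id, family_id = assignment$family,
                   group_id = assignment$group,
                   is_surplus = assignment$surplus)
  write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_group_assignment
#' @param n_a Group size recorded on the read assignment.
#' @export
read_group_assignment <- function(file, n_a = NA_integer_) {
  df <- read.csv(file, na.strings = c("", "NA"))
  out <- data.frame(id = df$animal_id, family = as.character(df$family_id),
                    group = as.character(df$group_id),
                    surplus = as.logical(df$is_surplus))
  .new_assignment(out, n_a, "file")
}

#' Export a genomic relationship matrix
#'
#' `format = "matrix"` writes the full matrix with an id header row and
#' column; `format = "triplet"` writes the long upper triangle
#' (`id1,id2,value`, diagonal included).
#'
#' @param grm A full `grm`.
#' @param file Path.
#' @param format `"matrix"` or `"triplet"`.
#' @export
write_grm <- function(grm, file, format = c("matrix", "triplet")) {
  format <- match.arg(format)
  if (grm$kind != "full") stop("only full GRMs can be exported")
  if (format == "matrix") {
    G <- grm$G
    dimnames(G) <- list(grm$ids, grm$ids)
    write.table(G, file, quote = FALSE, col.names = NA)
  } else {
    iu <- which(upper.tri(grm$G, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = grm$ids[iu[, 1]], id2 = grm$ids[iu[, 2]],
                     value = grm$G[iu])
    write.csv(df, file, row.names = FALSE)
  }
  invisible(file)
}
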