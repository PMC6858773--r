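# Group phenotypes and the design objects of the group-record model.

#' Construct group records
#'
#' A group record is the sum of the individual phenotypes of the group
#' members. The residual scaling of the group-record model is a diagonal
#' matrix whose entries equal the group sizes, because a sum of `k`
#' independent residuals has variance `k * sigma2_e`.
#'
#' @param phenotypes Phenotype table from [simulate_phenotypes()] (or any
#'   data.frame with columns id, y).
#' @param assignment A `group_assignment`; surplus animals are skipped.
#' @param ids Animal id order of the relationship matrix (columns of the
#'   incidence matrix). Default: `phenotypes$id`.
#' @return Object of class `group_records`: `group_id`, `size`, `y_star`,
#'   `members` (list of id vectors), `Z_star` (sparse groups x animals
#'   incidence), `R` (diagonal of the residual scaling) and `ids`.
#' @export
make_group_records <- function(phenotypes, assignment, ids = phenotypes$id) {
  grouped <- assignment[!assignment$surplus, , drop = FALSE]
  y <- phenotypes$y[match(grouped$id, phenotypes$id)]
  if (anyNA(y))
    stop(sprintf("grouped animal(s) without phenotype: %s",
                 paste(grouped$id[is.na(y)][1:min(5, sum(is.na(y)))],
                       collapse = ", ")))
  members <- split(grouped$id, grouped$group)
  y_by_group <- split(y, grouped$group)
  y_star <- vapply(y_by_group, sum, 0)
  size <- vapply(members, length, 0L)
  n_g <- length(members)
  col <- match(grouped$id, ids)
  if (anyNA(col)) stop("grouped animal(s) absent from `ids`")
  Z_star <- Matrix::sparseMatrix(
    i = match(grouped$group, names(members)), j = col, x = 1,
    dims = c(n_g, length(ids)))
  structure(list(group_id = names(members), size = size,
                 y_star = unname(y_star), members = members,
                 Z_star = Z_star, R = as.numeric(size),
                 ids = as.integer(ids)),
            class = "group_records")
}

#' @export
print.group_records <- function(x, ...) {
  cat(sprintf("<group_records> %d groups, sizes %s, %d animals in design\n",
              length(x$y_star),
              paste(unique(range(x$size)), collapse = "-"), length(x$ids)))
  invisible(x)
}

#' Export a group-record table
#'
#' @param records A `group_records`.
#' @param file CSV path.
#' @return The written data.frame, invisibly (group_id, size, y_star,
#'   comma-separated member ids).
#' @export
write_group_records <- function(records, file) {
  df <- data.frame(group_id = records$group_id, size = records$size,
                   y_star = records$y_star,
                   members = vapply(records$members,
                                    function(m) paste(m, collapse = " "), ""))
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}
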