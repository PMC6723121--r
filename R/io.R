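#' Plain-text import/export of simulation tables
#'
#' Tab-separated writers and readers for the stage outputs: pedigree
#' (columns `id`, `sire`, `dam`, `sex`, `generation`, `litter`; 0 = unknown
#' parent), phenotypes (`id`, `time`, `value`, `observed` as 1/0), pen
#' assignments, drop-out plans, group records (member ids comma-separated)
#' and the Legendre basis.
#'
#' @param x table to write.
#' @param file path of the TSV file.
#' @return readers return the corresponding `data.frame`; writers return
#'   `file` invisibly.
#' @name groupRR-io
NULL

.write_tsv <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname groupRR-io
#' @export
write_pedigree_tsv <- function(x, file) .write_tsv(x, file)

#' @rdname groupRR-io
#' @export
read_pedigree_tsv <- function(file) {
  ped <- read.table(file, header = TRUE, sep = "\t",
                    colClasses = c(sex = "character"))
  class(ped) <- c("pedigree", "data.frame")
  .check_pedigree(ped)
}

#' @rdname groupRR-io
#' @export
write_phenotypes_tsv <- function(x, file) {
  x$observed <- as.integer(x$observed)
  .write_tsv(x, file)
}

#' @rdname groupRR-io
#' @export
read_phenotypes_tsv <- function(file) {
  ph <- read.table(file, header = TRUE, sep = "\t")
  ph$observed <- as.logical(ph$observed)
  class(ph) <- c("phenotypes", "data.frame")
  ph
}

#' @rdname groupRR-io
#' @export
write_pens_tsv <- function(x, file) .write_tsv(x, file)

#' @rdname groupRR-io
#' @export
read_pens_tsv <- function(file) read.table(file, header = TRUE, sep = "\t")

#' @rdname groupRR-io
#' @export
write_dropout_tsv <- function(x, file) .write_tsv(x, file)

#' @rdname groupRR-io
#' @export
read_dropout_tsv <- function(file) {
  read.table(file, header = TRUE, sep = "\t",
             colClasses = c(strategy = "character"))
}

#' @rdname groupRR-io
#' @export
write_group_records_tsv <- function(x, file) {
  flat <- data.frame(pen = x$pen, time = x$time, y_star = x$y_star, n = x$n,
                     members = vapply(x$members, paste, character(1),
                                      collapse = ","))
  .write_tsv(flat, file)
}

#' @rdname groupRR-io
#' @export
read_group_records_tsv <- function(file) {
  flat <- read.table(file, header = TRUE, sep = "\t",
                     colClasses = c(members = "character"))
  out <- flat[, c("pen", "time", "y_star", "n")]
  out$members <- I(lapply(strsplit(flat$members, ","), as.integer))
  class(out) <- c("group_records", "data.frame")
  out
}

#' @rdname groupRR-io
#' @param L basis matrix from [legendre_matrix()].
#' @export
write_basis_tsv <- function(L, file) {
  .write_tsv(data.frame(time = attr(L, "time_points"), x = attr(L, "x"),
                        as.data.frame(unclass(L)[, , drop = FALSE])),
             file)
}
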