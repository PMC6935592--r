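# Readers and writers for the package's plain-text interchange formats:
# pedigree CSV (id, sire, dam, family), genotype CSV (first column id, one
# column per marker) and a PLINK-.raw-like whitespace format, phenotype CSV,
# dense relationship-matrix CSV, and QC reports as TSV.

#' Write / read a pedigree as CSV
#'
#' @param pedigree Tibble with `id`, `sire`, `dam`, `family`.
#' @param path File path.
#' @return `read_pedigree()` returns the pedigree tibble.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(d)
}

#' Write / read a genotype dosage matrix
#'
#' CSV with the individual id in the first column and one column per marker;
#' `format = "raw"` writes the whitespace-separated variant (header of marker
#' ids, rows of `id dosage dosage ...`).
#'
#' @param genotypes Dosage matrix with dimnames.
#' @param path File path.
#' @param format `"csv"` or `"raw"`.
#' @return `read_genotypes()` returns the dosage matrix.
#' @export
write_genotypes <- function(genotypes, path, format = c("csv", "raw")) {
  format <- match.arg(format)
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    utils::write.table(df, path, row.names = FALSE, quote = FALSE,
                       sep = " ", na = "NA")
  }
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, format = c("csv", "raw")) {
  format <- match.arg(format)
  d <- if (format == "csv") {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  m
}

#' Write / read a phenotype table as CSV
#'
#' @param phenotypes Tibble with `tree_id`, `site`, `block`, `family` and
#'   trait columns.
#' @param path File path.
#' @return `read_phenotypes()` returns the tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a dense relationship matrix as CSV
#'
#' @param R Square relationship matrix with ids on dimnames.
#' @param path File path.
#' @return `read_relationship()` returns the matrix.
#' @export
write_relationship <- function(R, path) {
  utils::write.csv(data.frame(id = rownames(R), R, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_relationship
#' @export
read_relationship <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a QC report as TSV
#'
#' @param report The `report` tibble from [qc_filter()].
#' @param path File path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, row.names = FALSE, quote = FALSE,
                     sep = "\t", na = "NA")
  invisible(path)
}
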