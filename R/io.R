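# Delimited-text interchange: first column sample id, second column group,
# remaining columns metabolites (tables) or ppm bin centers (spectra).

#' Write a metabolite table as tab-delimited text
#'
#' @param table A `metabolite_table`.
#' @param path Output file path.
#' @export
write_metabolite_table <- function(table, path) {
  stopifnot(inherits(table, "metabolite_table"))
  df <- data.frame(sample_id = table$sample_ids,
                   group = table$group_labels,
                   table$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metabolite table written by [write_metabolite_table()]
#'
#' @param path Input file path.
#' @return A `metabolite_table`.
#' @export
read_metabolite_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 3L || !all(c("sample_id", "group") %in% names(df)[1:2]))
    stop("malformed metabolite table file: ", path)
  metabolite_table(df$sample_id, df$group,
                   as.matrix(df[, -(1:2), drop = FALSE]))
}

#' Write binned spectra as tab-delimited text
#'
#' Bin centers become column headers (ppm, full precision, descending by
#' package convention).
#'
#' @param spectra A `binned_spectra`.
#' @param path Output file path.
#' @export
write_binned_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "binned_spectra"))
  m <- spectra$intensities
  colnames(m) <- format(spectra$bin_centers, trim = TRUE, digits = 15)
  df <- data.frame(sample_id = spectra$sample_ids,
                   group = spectra$group_labels, m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binned spectra written by [write_binned_spectra()]
#'
#' @param path Input file path.
#' @return A `binned_spectra`.
#' @export
read_binned_spectra <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 3L || !all(c("sample_id", "group") %in% names(df)[1:2]))
    stop("malformed binned spectra file: ", path)
  centers <- as.numeric(names(df)[-(1:2)])
  if (anyNA(centers)) stop("non-numeric bin center header in: ", path)
  binned_spectra(df$sample_id, df$group, centers,
                 as.matrix(df[, -(1:2), drop = FALSE]))
}

#' Write a similarity matrix as tab-delimited text
#'
#' @param sim Symmetric numeric matrix with metabolite dimnames.
#' @param path Output file path.
#' @export
write_similarity_matrix <- function(sim, path) {
  df <- data.frame(metabolite = rownames(sim), sim, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_matrix()]
#'
#' @param path Input file path.
#' @return A symmetric numeric matrix.
#' @export
read_similarity_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
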