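#' Construct a binned-spectra object
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param group_labels Character vector parallel to `sample_ids`.
#' @param bin_centers Strictly monotone numeric vector of ppm bin centers.
#'   By package convention exported spectra use descending ppm.
#' @param intensities Numeric samples x bins matrix.
#' @return An object of class `binned_spectra`.
#' @export
binned_spectra <- function(sample_ids, group_labels, bin_centers,
                           intensities) {
  sample_ids <- as.character(sample_ids)
  group_labels <- as.character(group_labels)
  bin_centers <- as.numeric(bin_centers)
  intensities <- as.matrix(intensities)
  if (length(sample_ids) != nrow(intensities) ||
      length(group_labels) != nrow(intensities))
    stop("row count must match sample ids and group labels")
  if (length(bin_centers) != ncol(intensities))
    stop("column count must equal the number of bin centers")
  d <- diff(bin_centers)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("bin centers must be strictly monotone")
  rownames(intensities) <- sample_ids
  colnames(intensities) <- format(bin_centers, trim = TRUE, digits = 8)
  structure(list(sample_ids = sample_ids, group_labels = group_labels,
                 bin_centers = bin_centers, intensities = intensities),
            class = "binned_spectra")
}

#' @export
print.binned_spectra <- function(x, ...) {
  cat("Binned spectra:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "bins,",
      sprintf("%.3f-%.3f ppm\n", min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' Remove chemical-shift regions from binned spectra
#'
#' Bins whose centers fall inside any of the (closed) ppm intervals are
#' dropped; the order of the remaining bins is preserved. The conventional
#' use is removal of the residual water signal (default window in
#' [default_pipeline_config()] is 4.7-5.1 ppm).
#'
#' @param spectra A `binned_spectra` object.
#' @param regions List of length-2 numeric vectors `(low, high)` in ppm.
#' @return A `binned_spectra` object without the excluded bins.
#' @export
exclude_regions <- function(spectra, regions) {
  stopifnot(inherits(spectra, "binned_spectra"))
  if (length(regions) == 0L) return(spectra)
  drop <- rep(FALSE, length(spectra$bin_centers))
  for (r in regions) {
    if (length(r) != 2L) stop("each region must be a (low, high) pair")
    r <- sort(as.numeric(r))
    drop <- drop | (spectra$bin_centers >= r[1L] &
                    spectra$bin_centers <= r[2L])
  }
  if (all(drop)) stop("region exclusion would remove every bin")
  binned_spectra(spectra$sample_ids, spectra$group_labels,
                 spectra$bin_centers[!drop],
                 spectra$intensities[, !drop, drop = FALSE])
}

#' Normalize each spectrum to a constant total area
#'
#' Scales every row so its summed intensity equals `target`, removing
#' overall concentration/dilution differences between samples while
#' preserving within-row intensity ratios exactly.
#'
#' @param spectra A `binned_spectra` object.
#' @param target Positive row-sum after normalization.
#' @return A `binned_spectra` object with normalized rows.
#' @export
normalize_total_area <- function(spectra, target = 1.0) {
  stopifnot(inherits(spectra, "binned_spectra"))
  if (target <= 0) stop("'target' must be positive")
  sums <- rowSums(spectra$intensities)
  bad <- which(sums <= 0)
  if (length(bad))
    stop("non-positive total intensity for sample(s): ",
         paste(spectra$sample_ids[bad], collapse = ", "))
  binned_spectra(spectra$sample_ids, spectra$group_labels,
                 spectra$bin_centers,
                 spectra$intensities * (target / sums))
}

#' Column-wise scaling for multivariate modeling
#'
#' `center` subtracts the column mean; `unit_variance` additionally divides
#' by the column SD (autoscaling); `pareto` divides by the square root of
#' the SD, the common compromise for NMR data that damps intense signals
#' without blowing up baseline noise. The applied statistics are stored as
#' attributes so the transform can be inverted ([unscale_columns()]) or
#' applied to new data ([apply_scaling()]).
#'
#' Columns with zero variance carry no discriminant information; for the
#' variance-based methods they are dropped with a warning.
#'
#' @param x Numeric matrix (samples x variables).
#' @param method One of `"center"`, `"unit_variance"`, `"pareto"`.
#' @return The scaled matrix with attributes `col_center`, `col_scale`,
#'   `scaling_method` and `dropped_columns`.
#' @export
scale_columns <- function(x, method = c("center", "unit_variance",
                                        "pareto")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  ctr <- colMeans(x)
  sds <- apply(x, 2L, sd)
  dropped <- character(0)
  if (method != "center") {
    zero <- sds == 0
    if (any(zero)) {
      dropped <- colnames(x)[zero]
      if (is.null(dropped)) dropped <- as.character(which(zero))
      warning("dropping ", sum(zero), " zero-variance column(s): ",
              paste(dropped, collapse = ", "))
      x <- x[, !zero, drop = FALSE]
      ctr <- ctr[!zero]
      sds <- sds[!zero]
    }
  }
  scl <- switch(method,
                center = rep(1, ncol(x)),
                unit_variance = sds,
                pareto = sqrt(sds))
  out <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  attr(out, "col_center") <- ctr
  attr(out, "col_scale") <- scl
  attr(out, "scaling_method") <- method
  attr(out, "dropped_columns") <- dropped
  out
}

#' Apply stored scaling statistics to new data
#'
#' @param x New samples x variables matrix with the same variables as the
#'   matrix that produced `scaled` (dropped columns are dropped here too).
#' @param scaled A matrix returned by [scale_columns()].
#' @return The transformed matrix.
#' @export
apply_scaling <- function(x, scaled) {
  ctr <- attr(scaled, "col_center")
  scl <- attr(scaled, "col_scale")
  if (is.null(ctr)) stop("'scaled' carries no scaling statistics")
  x <- as.matrix(x)
  if (!is.null(colnames(scaled)) && !is.null(colnames(x)))
    x <- x[, colnames(scaled), drop = FALSE]
  if (ncol(x) != length(ctr)) stop("column mismatch with stored statistics")
  sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
}

#' Invert a column scaling
#'
#' @param scaled A matrix returned by [scale_columns()].
#' @return The original matrix (minus any dropped zero-variance columns).
#' @export
unscale_columns <- function(scaled) {
  ctr <- attr(scaled, "col_center")
  scl <- attr(scaled, "col_scale")
  if (is.null(ctr)) stop("'scaled' carries no scaling statistics")
  out <- sweep(sweep(scaled, 2L, scl, "*"), 2L, ctr, "+")
  attr(out, "col_center") <- NULL
  attr(out, "col_scale") <- NULL
  attr(out, "scaling_method") <- NULL
  attr(out, "dropped_columns") <- NULL
  out
}
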