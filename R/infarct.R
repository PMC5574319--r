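#' Edema-corrected infarct volume percentage
#'
#' `I% = (Vc - Vi) / Vc * 100`, where `Vc` is the volume of the intact
#' contralateral (left) hemisphere and `Vi` the volume of the intact
#' regions of the ipsilateral (right) hemisphere. Using the intact
#' ipsilateral volume rather than the infarct itself corrects for edema.
#' The result is scale-invariant and decreases in `Vi`; negative values
#' (possible with measurement noise when `Vi > Vc`) are returned as-is
#' with a warning rather than clamped.
#'
#' @param v_contralateral Positive volume(s) `Vc` in mm^3.
#' @param v_intact_ipsilateral Non-negative volume(s) `Vi` in mm^3. Values
#'   above `1.5 * Vc` (beyond any plausible edema allowance) trigger a
#'   warning.
#' @return Numeric percentage(s).
#' @export
infarct_percentage <- function(v_contralateral, v_intact_ipsilateral) {
  vc <- as.numeric(v_contralateral)
  vi <- as.numeric(v_intact_ipsilateral)
  if (length(vc) != length(vi))
    stop("'v_contralateral' and 'v_intact_ipsilateral' lengths differ")
  if (anyNA(vc) || anyNA(vi)) stop("volumes must not be missing")
  if (any(vc <= 0)) stop("'v_contralateral' must be positive")
  if (any(vi < 0)) stop("'v_intact_ipsilateral' must be non-negative")
  if (any(vi > 1.5 * vc))
    warning("Vi exceeds 1.5 * Vc for some measurement(s); check units")
  out <- (vc - vi) / vc * 100
  if (any(out < 0))
    warning("negative infarct percentage(s): Vi > Vc")
  out
}

#' Compute infarct percentages from a two-column delimited file
#'
#' The file must have a header and two numeric columns `(Vc, Vi)`.
#'
#' @param path Input file path.
#' @return The input data.frame with an added `infarct_percent` column.
#' @export
read_infarct_file <- function(path) {
  df <- read.delim(path)
  if (ncol(df) < 2L) stop("expected two columns (Vc, Vi) in: ", path)
  df$infarct_percent <- infarct_percentage(df[[1L]], df[[2L]])
  df
}
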