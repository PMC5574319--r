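# Shared-and-unique-structure (SUS) comparison of two OPLS-DA models that
# share a reference class (e.g. two treatments each compared with the
# disease model group).

#' SUS-plot profiles from two models with a common reference class
#'
#' Computes the per-variable `corr(t_p, X)` profile of each model (see
#' [splot()]) and aligns signs so that a positive correlation always means
#' "elevated in the non-reference class". Plotting `corr_b` against
#' `corr_a` gives the SUS-plot: effects shared by both comparisons fall on
#' the diagonals, model-unique effects near the axes.
#'
#' @param model_a,model_b Fitted `opls_model`s sharing `reference` as one
#'   of their classes.
#' @param X_a,X_b Centered unscaled matrices the models were fitted on
#'   (used for the correlation profiles).
#' @param reference Name of the shared reference class.
#' @param vip_a,vip_b Optional named VIP vectors; computed from the models
#'   when omitted.
#' @return A data.frame with columns `metabolite`, `corr_a`, `corr_b`,
#'   `vip_a`, `vip_b` over the shared variable namespace.
#' @export
sus_profiles <- function(model_a, model_b, X_a, X_b, reference,
                         vip_a = NULL, vip_b = NULL) {
  stopifnot(inherits(model_a, "opls_model"),
            inherits(model_b, "opls_model"))
  for (m in list(model_a, model_b))
    if (!reference %in% m$classes)
      stop("both models must include the reference class '", reference, "'")

  sp_a <- splot(model_a, X_a)
  sp_b <- splot(model_b, X_b)
  shared <- intersect(sp_a$variable, sp_b$variable)
  if (length(shared) == 0L)
    stop("models share no variables")

  # positive corr = elevated in the non-reference class
  flip_a <- if (model_a$positive_class == reference) -1 else 1
  flip_b <- if (model_b$positive_class == reference) -1 else 1
  if (is.null(vip_a)) vip_a <- vip(model_a)
  if (is.null(vip_b)) vip_b <- vip(model_b)

  data.frame(
    metabolite = shared,
    corr_a = flip_a * sp_a$corr[match(shared, sp_a$variable)],
    corr_b = flip_b * sp_b$corr[match(shared, sp_b$variable)],
    vip_a = unname(vip_a[shared]),
    vip_b = unname(vip_b[shared]))
}

# minimal angular distance (degrees) from direction theta to the line
# through the origin at angle phi (lines are 180-degree periodic)
.angle_to_line <- function(theta, phi) {
  d <- abs((theta - phi) %% 180)
  pmin(d, 180 - d)
}

#' Classify SUS-plot points into shared and unique regions
#'
#' Only metabolites with `max(vip_a, vip_b) > vip_cut` are classified.
#' With point angle `theta = atan2(corr_b, corr_a)`: points within
#' `diag_angle_deg` of the +45 degree line are `shared_positive`, within
#' `diag_angle_deg` of the -45 degree line `shared_negative`, within
#' `axis_angle_deg` of the x-axis (and `|corr_a| >= corr_floor`)
#' `unique_a`, similarly `unique_b`; points with both correlations below
#' `corr_floor` in magnitude are `unclassified` rather than forced into a
#' region, as are points falling between regions.
#'
#' @param points Data.frame from [sus_profiles()].
#' @param vip_cut VIP selection cut (default 1).
#' @param axis_angle_deg,diag_angle_deg Angular half-widths of the axis
#'   and diagonal regions, both in (0, 45) degrees.
#' @param corr_floor Minimum correlation magnitude for a classifiable
#'   point.
#' @return An object of class `sus_classification`: named character vector
#'   over the VIP-selected metabolites with values in `shared_positive`,
#'   `shared_negative`, `unique_a`, `unique_b`, `unclassified`; the
#'   thresholds used are stored as attributes.
#' @export
classify_shared_unique <- function(points, vip_cut = 1.0,
                                   axis_angle_deg = 15,
                                   diag_angle_deg = 20,
                                   corr_floor = 0.3) {
  if (axis_angle_deg <= 0 || axis_angle_deg >= 45 ||
      diag_angle_deg <= 0 || diag_angle_deg >= 45)
    stop("angles must lie strictly between 0 and 45 degrees")
  sel <- pmax(points$vip_a, points$vip_b) > vip_cut
  pts <- points[sel, , drop = FALSE]
  theta <- atan2(pts$corr_b, pts$corr_a) * 180 / pi
  region <- rep("unclassified", nrow(pts))
  near_origin <- abs(pts$corr_a) < corr_floor & abs(pts$corr_b) < corr_floor
  on_diag_pos <- .angle_to_line(theta, 45) <= diag_angle_deg
  on_diag_neg <- .angle_to_line(theta, -45) <= diag_angle_deg
  on_axis_a <- .angle_to_line(theta, 0) <= axis_angle_deg &
    abs(pts$corr_a) >= corr_floor
  on_axis_b <- .angle_to_line(theta, 90) <= axis_angle_deg &
    abs(pts$corr_b) >= corr_floor
  region[on_axis_b] <- "unique_b"
  region[on_axis_a] <- "unique_a"
  region[on_diag_neg] <- "shared_negative"
  region[on_diag_pos] <- "shared_positive"
  region[near_origin] <- "unclassified"
  structure(setNames(region, pts$metabolite),
            class = "sus_classification",
            vip_cut = vip_cut, axis_angle_deg = axis_angle_deg,
            diag_angle_deg = diag_angle_deg, corr_floor = corr_floor)
}

#' Region counts and memberships of a SUS classification
#'
#' @param classification A `sus_classification`.
#' @return A list with `counts` (named integer vector over
#'   `shared_positive`, `shared_negative`, `unique_a`, `unique_b`,
#'   `unclassified`) and `members` (sorted name lists per region).
#' @export
venn_counts <- function(classification) {
  regions <- c("shared_positive", "shared_negative", "unique_a",
               "unique_b", "unclassified")
  cls <- unclass(classification)
  members <- lapply(regions, function(r) sort(names(cls)[cls == r]))
  names(members) <- regions
  counts <- vapply(members, length, 0L)
  list(counts = counts, members = members)
}

#' Export a SUS scatter as delimited text
#'
#' @param points Data.frame from [sus_profiles()].
#' @param classification Matching `sus_classification`.
#' @param path Output file path.
#' @export
write_sus_table <- function(points, classification, path) {
  cls <- unclass(classification)
  points$region <- ifelse(points$metabolite %in% names(cls),
                          cls[points$metabolite], "below_vip_cut")
  write.table(points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
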