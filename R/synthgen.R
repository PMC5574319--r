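#' Define a synthetic study design
#'
#' A study design states the group structure, the planted group effects and
#' the correlation structure from which synthetic metabolite tables are
#' drawn. The first element of `groups` is the reference group; all effects
#' are standardized mean shifts relative to it, expressed in units of the
#' within-group standard deviation on the latent (log) scale.
#'
#' @param groups Character vector of group names; the first is the reference.
#' @param n_per_group Positive integer, samples per group.
#' @param metabolites Character vector of unique metabolite names.
#' @param effects Optional data.frame with columns `metabolite`, `group`,
#'   `shift` giving the standardized mean shift of a metabolite in a group
#'   relative to the reference. Unlisted combinations have shift 0. Shifts
#'   for the reference group must be 0.
#' @param correlation_blocks Optional list of blocks, each a list with
#'   elements `metabolites` (a subset of `metabolites`) and `rho` (the
#'   common within-block correlation, in `[0, 1)`). Blocks must be disjoint.
#' @param noise_sd Positive within-group standard deviation on the latent
#'   scale. The default 0.2 on the log scale corresponds to a ~20%
#'   coefficient of variation, typical of NMR metabolite quantifications.
#' @param base_log_mean Baseline log-concentration of every metabolite in
#'   the reference group (arbitrary units).
#' @param seed Integer seed making the generated table reproducible.
#'
#' @return An object of class `study_design`.
#' @seealso [generate_metabolite_table()]
#' @export
study_design <- function(groups, n_per_group, metabolites,
                         effects = NULL, correlation_blocks = list(),
                         noise_sd = 0.2, base_log_mean = log(10),
                         seed = 1L) {
  groups <- as.character(groups)
  metabolites <- as.character(metabolites)
  if (length(groups) < 1L || anyDuplicated(groups))
    stop("'groups' must be a non-empty vector of unique names")
  if (length(metabolites) < 1L)
    stop("'metabolites' must be non-empty")
  if (anyDuplicated(metabolites))
    stop("metabolite names must be unique")
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 1L)
    stop("'n_per_group' must be a positive integer")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be positive")

  if (is.null(effects)) {
    effects <- data.frame(metabolite = character(0), group = character(0),
                          shift = numeric(0))
  }
  stopifnot(all(c("metabolite", "group", "shift") %in% names(effects)))
  if (!all(effects$metabolite %in% metabolites))
    stop("effect table references unknown metabolite(s): ",
         paste(setdiff(effects$metabolite, metabolites), collapse = ", "))
  if (!all(effects$group %in% groups))
    stop("effect table references unknown group(s)")
  ref <- groups[1L]
  if (any(effects$group == ref & effects$shift != 0))
    stop("reference group '", ref, "' must have all shifts equal to 0")

  seen <- character(0)
  for (b in correlation_blocks) {
    if (!all(c("metabolites", "rho") %in% names(b)))
      stop("each correlation block needs 'metabolites' and 'rho'")
    if (!all(b$metabolites %in% metabolites))
      stop("correlation block references unknown metabolite(s)")
    if (b$rho < 0 || b$rho >= 1)
      stop("within-block correlation must lie in [0, 1)")
    if (any(b$metabolites %in% seen))
      stop("correlation blocks must be disjoint")
    seen <- c(seen, b$metabolites)
  }

  structure(
    list(groups = groups, n_per_group = n_per_group,
         metabolites = metabolites, effects = effects,
         correlation_blocks = correlation_blocks,
         noise_sd = noise_sd, base_log_mean = base_log_mean,
         seed = as.integer(seed)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$groups), "groups x", x$n_per_group,
      "samples,", length(x$metabolites), "metabolites\n")
  cat("  groups:", paste(x$groups, collapse = ", "),
      "(reference:", paste0(x$groups[1L], ")\n"))
  cat("  planted effects:", nrow(x$effects),
      " correlation blocks:", length(x$correlation_blocks), "\n")
  invisible(x)
}

# shift matrix (groups x metabolites) from the long effect table
.design_shift_matrix <- function(design) {
  s <- matrix(0, length(design$groups), length(design$metabolites),
              dimnames = list(design$groups, design$metabolites))
  if (nrow(design$effects))
    s[cbind(design$effects$group, design$effects$metabolite)] <-
      design$effects$shift
  s
}

# correlation matrix implied by the design's blocks
.design_correlation <- function(design) {
  m <- length(design$metabolites)
  R <- diag(m)
  dimnames(R) <- list(design$metabolites, design$metabolites)
  for (b in design$correlation_blocks) {
    idx <- match(b$metabolites, design$metabolites)
    R[idx, idx] <- b$rho
    diag(R)[idx] <- 1
  }
  R
}

#' Draw a synthetic metabolite table from a study design
#'
#' Concentrations follow a multivariate normal model on the log scale,
#' exponentiated to give positive, right-skewed values: for sample i in
#' group g, `log(value) = base_log_mean + shift[g, ] * noise_sd + e`, with
#' `e ~ N(0, noise_sd^2 * R)` and `R` the block-correlation matrix. The
#' planted standardized effects are therefore exact on the log scale. With
#' `scale = "linear"` the same model is applied additively around
#' `exp(base_log_mean)` and negative draws are truncated at zero.
#'
#' @param design A [study_design()].
#' @param scale `"log-normal"` (default) or `"linear"`.
#' @return A `metabolite_table`: list with `sample_ids`, `group_labels`,
#'   `values` (samples x metabolites, non-negative) and `metabolite_names`.
#' @export
generate_metabolite_table <- function(design,
                                      scale = c("log-normal", "linear")) {
  stopifnot(inherits(design, "study_design"))
  scale <- match.arg(scale)
  set.seed(design$seed)

  g <- design$groups
  n <- design$n_per_group
  m <- length(design$metabolites)
  shifts <- .design_shift_matrix(design)
  L <- chol(.design_correlation(design))

  rows <- vector("list", length(g))
  labels <- rep(g, each = n)
  for (k in seq_along(g)) {
    z <- matrix(rnorm(n * m), n, m) %*% L * design$noise_sd
    if (scale == "log-normal") {
      mu <- design$base_log_mean + shifts[k, ] * design$noise_sd
      rows[[k]] <- exp(sweep(z, 2L, mu, "+"))
    } else {
      base <- exp(design$base_log_mean)
      mu <- base * (1 + shifts[k, ] * design$noise_sd)
      rows[[k]] <- pmax(sweep(base * z, 2L, mu, "+"), 0)
    }
  }
  values <- do.call(rbind, rows)
  ids <- paste0(labels, "_", sequence(rep(n, length(g))))
  dimnames(values) <- list(ids, design$metabolites)

  metabolite_table(ids, labels, values, design$metabolites)
}

#' Construct a metabolite table
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param group_labels Character vector parallel to `sample_ids`.
#' @param values Numeric samples x metabolites matrix, non-negative, no
#'   missing values.
#' @param metabolite_names Optional; defaults to `colnames(values)`.
#' @return An object of class `metabolite_table`.
#' @export
metabolite_table <- function(sample_ids, group_labels, values,
                             metabolite_names = colnames(values)) {
  sample_ids <- as.character(sample_ids)
  group_labels <- as.character(group_labels)
  values <- as.matrix(values)
  if (length(sample_ids) != nrow(values) ||
      length(group_labels) != nrow(values))
    stop("row count must equal the number of sample ids and group labels")
  if (anyNA(values)) stop("metabolite values must not contain missing data")
  if (is.null(metabolite_names)) stop("metabolite names are required")
  metabolite_names <- as.character(metabolite_names)
  if (anyDuplicated(metabolite_names)) stop("metabolite names must be unique")
  if (length(metabolite_names) != ncol(values))
    stop("metabolite name count must match the column count")
  dimnames(values) <- list(sample_ids, metabolite_names)
  structure(list(sample_ids = sample_ids, group_labels = group_labels,
                 values = values, metabolite_names = metabolite_names),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("Metabolite table:", nrow(x$values), "samples x", ncol(x$values),
      "metabolites\n")
  cat("  groups:", paste(sprintf("%s (%d)", names(table(x$group_labels)),
                                 table(x$group_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Spectral rendering parameters
#'
#' Describes a fictional but ppm-plausible peak library: each metabolite
#' maps to one or more Lorentzian peaks given as (center ppm, relative
#' amplitude, half-width at half-maximum in ppm).
#'
#' @param ppm_range Length-2 numeric, the observed chemical-shift window.
#' @param points Number of grid points the continuous spectrum is evaluated
#'   on before binning.
#' @param peaks Named list: metabolite -> matrix/data.frame with columns
#'   `center`, `amplitude`, `hwhm`.
#' @param baseline_sd Standard deviation of the Gaussian baseline noise
#'   added per bin.
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(ppm_range = c(0.5, 9.5), points = 4096L,
                            peaks, baseline_sd = 0.001) {
  stopifnot(length(ppm_range) == 2L, ppm_range[1L] < ppm_range[2L])
  points <- as.integer(points)
  if (points < 16L) stop("'points' must be at least 16")
  if (baseline_sd < 0) stop("'baseline_sd' must be non-negative")
  peaks <- lapply(peaks, function(p) {
    p <- as.data.frame(p)
    stopifnot(all(c("center", "amplitude", "hwhm") %in% names(p)))
    if (any(p$center < ppm_range[1L] | p$center > ppm_range[2L]))
      stop("all peak centers must lie inside the ppm range")
    if (any(p$amplitude <= 0) || any(p$hwhm <= 0))
      stop("peak amplitudes and widths must be strictly positive")
    p
  })
  structure(list(ppm_range = as.numeric(ppm_range), points = points,
                 peaks = peaks, baseline_sd = baseline_sd),
            class = "spectral_params")
}

#' Random ppm-plausible peak library for a set of metabolites
#'
#' Assigns each metabolite 1-3 Lorentzian peaks at random positions in the
#' ppm window with realistic line widths (~2.5 Hz at 500 MHz, i.e. 0.005
#' ppm). The library is fictional: it does not reproduce real chemical
#' shifts.
#'
#' @param metabolites Character vector.
#' @param ppm_range,points,baseline_sd Passed to [spectral_params()].
#' @param seed Integer seed.
#' @return A `spectral_params` object.
#' @export
random_peak_library <- function(metabolites, ppm_range = c(0.5, 9.5),
                                points = 4096L, baseline_sd = 0.001,
                                seed = 1L) {
  set.seed(seed)
  pad <- 0.1 * diff(ppm_range)
  peaks <- lapply(metabolites, function(m) {
    k <- sample(1:3, 1L)
    data.frame(
      center = runif(k, ppm_range[1L] + pad, ppm_range[2L] - pad),
      amplitude = runif(k, 0.5, 2),
      hwhm = runif(k, 0.003, 0.008))
  })
  names(peaks) <- metabolites
  spectral_params(ppm_range, points, peaks, baseline_sd)
}

#' Render binned spectra from a metabolite table
#'
#' Each sample's continuous spectrum is the sum over metabolites of
#' `value * amplitude * L(ppm)`, where `L` is a unit-area Lorentzian
#' truncated at `support_hwhm` half-widths from its center (the truncation
#' keeps >99% of the analytic area at the default and gives peaks compact
#' support). The spectrum is integrated into contiguous bins of width
#' `bin_width`; independent Gaussian baseline noise is added per bin. Bin
#' centers are reported in descending ppm, the NMR plotting convention.
#'
#' @param table A `metabolite_table`.
#' @param sp A [spectral_params()] object covering the table's metabolites.
#' @param bin_width Bin width in ppm; must be positive and smaller than the
#'   ppm range.
#' @param support_hwhm Peaks are truncated beyond this many half-widths.
#' @param seed Optional integer seed for the baseline noise.
#' @return A [binned_spectra()] object.
#' @export
render_binned_spectra <- function(table, sp, bin_width = 0.04,
                                  support_hwhm = 100, seed = NULL) {
  stopifnot(inherits(table, "metabolite_table"),
            inherits(sp, "spectral_params"))
  rng <- sp$ppm_range
  if (bin_width <= 0 || bin_width >= diff(rng))
    stop("'bin_width' must be positive and smaller than the ppm range")
  missing_pk <- setdiff(table$metabolite_names, names(sp$peaks))
  if (length(missing_pk))
    stop("no peaks defined for: ", paste(missing_pk, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  x <- seq(rng[1L], rng[2L], length.out = sp$points)
  dx <- x[2L] - x[1L]
  # metabolite x grid-point profile matrix of unit-concentration responses
  prof <- matrix(0, length(table$metabolite_names), sp$points,
                 dimnames = list(table$metabolite_names, NULL))
  for (m in table$metabolite_names) {
    pk <- sp$peaks[[m]]
    for (i in seq_len(nrow(pk))) {
      g <- pk$hwhm[i]; c0 <- pk$center[i]
      d <- x - c0
      lor <- pk$amplitude[i] * (g / pi) / (d * d + g * g)
      lor[abs(d) > support_hwhm * g] <- 0
      prof[m, ] <- prof[m, ] + lor
    }
  }
  signal <- table$values %*% prof  # samples x grid points

  breaks <- seq(rng[1L], rng[2L], by = bin_width)
  if (breaks[length(breaks)] < rng[2L])
    breaks <- c(breaks, rng[2L])  # last bin absorbs the remainder
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  # grid-point -> bin indicator matrix; intensities by simple quadrature
  B <- matrix(0, sp$points, nb)
  B[cbind(seq_len(sp$points), idx)] <- 1
  intens <- (signal %*% B) * dx
  if (sp$baseline_sd > 0)
    intens <- intens + matrix(rnorm(length(intens), sd = sp$baseline_sd),
                              nrow(intens), ncol(intens))
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2

  ord <- order(centers, decreasing = TRUE)
  binned_spectra(table$sample_ids, table$group_labels,
                 centers[ord], intens[, ord, drop = FALSE])
}

#' Generate a synthetic structural-similarity matrix
#'
#' Related pairs (candidate substrate-product partners) get similarity
#' `high`; every other off-diagonal entry is `|N(0, low_sd)|` clipped below
#' `high / 2`, so that a threshold anywhere in `[high/2, high]` recovers
#' exactly the planted pairs. The matrix is symmetric with unit diagonal.
#'
#' @param metabolites Character vector of names.
#' @param related_pairs List of length-2 character vectors (or a 2-column
#'   matrix) of structurally related metabolites.
#' @param high Similarity assigned to related pairs, in `(0, 1]`.
#' @param low_sd Scale of the unrelated background similarities.
#' @param seed Integer seed.
#' @return A symmetric numeric matrix with entries in `[0, 1]`.
#' @export
generate_similarity_matrix <- function(metabolites, related_pairs = list(),
                                       high = 0.9, low_sd = 0.1, seed = 1L) {
  metabolites <- as.character(metabolites)
  if (high <= 0 || high > 1) stop("'high' must lie in (0, 1]")
  if (is.matrix(related_pairs))
    related_pairs <- split(related_pairs, seq_len(nrow(related_pairs)))
  for (p in related_pairs)
    if (length(p) != 2L || !all(p %in% metabolites))
      stop("related pair references unknown metabolite(s): ",
           paste(p, collapse = ", "))
  set.seed(seed)
  m <- length(metabolites)
  S <- matrix(0, m, m, dimnames = list(metabolites, metabolites))
  upper <- upper.tri(S)
  bg <- pmin(abs(rnorm(sum(upper), sd = low_sd)), high / 2 * (1 - 1e-9))
  S[upper] <- bg
  S <- S + t(S)
  diag(S) <- 1
  for (p in related_pairs) {
    S[p[1L], p[2L]] <- high
    S[p[2L], p[1L]] <- high
  }
  S
}
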