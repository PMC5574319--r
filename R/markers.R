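# Differential-metabolite evidence from a fitted OPLS-DA model: S-plot
# coordinates, VIP, and BH-adjusted fold changes.

#' S-plot coordinates: covariance and correlation with the predictive score
#'
#' For each variable j, `cov_j = t_p' x_j / (n - 1)` and
#' `corr_j = cov_j / (sd(t_p) * sd(x_j))`, computed from centered,
#' unscaled data so that `corr` is a true Pearson correlation. Reliable
#' high-magnitude markers sit far from the origin in the upper-right
#' (elevated in the positive-score class) or lower-left quadrant.
#'
#' @param model An `opls_model`.
#' @param X_centered Column-centered (unscaled) matrix with the model's
#'   variables and samples.
#' @return A data.frame with columns `variable`, `cov`, `corr`. Variables
#'   with zero SD are omitted with a warning.
#' @export
splot <- function(model, X_centered) {
  stopifnot(inherits(model, "opls_model"))
  X <- as.matrix(X_centered)
  if (nrow(X) != length(model$predictive_scores))
    stop("sample count mismatch between model and matrix")
  if (!is.null(colnames(X))) {
    if (!all(model$variable_names %in% colnames(X)))
      stop("matrix is missing model variables")
    X <- X[, model$variable_names, drop = FALSE]
  } else if (ncol(X) != length(model$variable_names)) {
    stop("variable count mismatch between model and matrix")
  }
  t_p <- model$predictive_scores
  n <- length(t_p)
  sds <- apply(X, 2L, sd)
  keep <- sds > 0
  if (!all(keep))
    warning("omitting ", sum(!keep), " zero-variance variable(s) from S-plot")
  X <- X[, keep, drop = FALSE]
  covs <- drop(crossprod(X, t_p)) / (n - 1)
  corrs <- covs / (sd(t_p) * sds[keep])
  data.frame(variable = model$variable_names[keep],
             cov = unname(covs), corr = unname(corrs))
}

#' Variable importance in projection (VIP) for the predictive component
#'
#' Single-predictive-component VIP: `VIP_j = sqrt(p * w_j^2 / sum(w^2))`
#' with `w` the predictive weight vector and `p` the number of variables,
#' so the mean squared VIP is exactly 1. The conventional selection cut is
#' VIP > 1.
#'
#' @param model A fitted `opls_model` with non-zero explained class
#'   variance.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  w <- model$weights
  if (model$r2y <= 0 || sum(w * w) < 1e-15)
    stop("degenerate model: no explained class variance")
  sqrt(length(w) * w^2 / sum(w^2))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort the m p-values increasingly, form
#' `p_(i) * m / i`, enforce monotonicity by a cumulative minimum from the
#' largest rank down, cap at 1, and map back to the input order.
#'
#' @param p_values Numeric vector with entries in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Fold changes with BH-adjusted p-values against a reference group
#'
#' For each metabolite, `fold_change = mean(group_a) / mean(group_ref)`
#' (conventionally sham or drug-treated over the disease model group), a
#' raw two-sided p-value from Welch's t-test (pooled-variance Student test
#' available via `var_equal = TRUE`), and Benjamini-Hochberg adjusted
#' p-values over the whole table.
#'
#' @param table A `metabolite_table`.
#' @param group_a Numerator group name.
#' @param group_ref Denominator (reference) group name.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A data.frame with columns `metabolite`, `fold_change`, `raw_p`,
#'   `adjusted_p`.
#' @export
fold_change_table <- function(table, group_a, group_ref,
                              var_equal = FALSE) {
  stopifnot(inherits(table, "metabolite_table"))
  for (g in c(group_a, group_ref)) {
    if (sum(table$group_labels == g) < 2L)
      stop("group '", g, "' needs at least 2 samples")
  }
  A <- table$values[table$group_labels == group_a, , drop = FALSE]
  R <- table$values[table$group_labels == group_ref, , drop = FALSE]
  mean_ref <- colMeans(R)
  zero_ref <- which(mean_ref == 0)
  if (length(zero_ref))
    stop("zero reference mean for metabolite(s): ",
         paste(table$metabolite_names[zero_ref], collapse = ", "))
  fc <- colMeans(A) / mean_ref
  raw_p <- vapply(seq_len(ncol(A)), function(j) {
    tryCatch(t.test(A[, j], R[, j], var.equal = var_equal)$p.value,
             error = function(e) 1)  # both groups constant
  }, 0)
  data.frame(metabolite = table$metabolite_names,
             fold_change = unname(fc),
             raw_p = raw_p,
             adjusted_p = bh_adjust(raw_p))
}

#' Combined marker evidence table
#'
#' Joins S-plot coordinates, VIP and fold-change statistics for one
#' model-versus-reference comparison, and flags selected markers by the
#' configurable rule `|corr| >= corr_cut & VIP > vip_cut &
#' adjusted_p < alpha`.
#'
#' @param model An `opls_model` fitted on the comparison's samples.
#' @param X_centered Centered unscaled matrix for the S-plot.
#' @param fold_changes Output of [fold_change_table()] for the same
#'   variables (matched by name; variables without fold-change rows get
#'   `NA`).
#' @param corr_cut,vip_cut,alpha Selection thresholds.
#' @return A data.frame with one row per variable: `metabolite`, `cov`,
#'   `corr`, `abs_corr` (the loading-plot color key), `vip`,
#'   `fold_change`, `raw_p`, `adjusted_p`, `selected`.
#' @export
marker_table <- function(model, X_centered, fold_changes = NULL,
                         corr_cut = 0.6, vip_cut = 1.0, alpha = 0.05) {
  sp <- splot(model, X_centered)
  v <- vip(model)
  out <- data.frame(metabolite = sp$variable, cov = sp$cov, corr = sp$corr,
                    abs_corr = abs(sp$corr),
                    vip = unname(v[sp$variable]))
  if (!is.null(fold_changes)) {
    idx <- match(out$metabolite, fold_changes$metabolite)
    out$fold_change <- fold_changes$fold_change[idx]
    out$raw_p <- fold_changes$raw_p[idx]
    out$adjusted_p <- fold_changes$adjusted_p[idx]
    out$selected <- !is.na(out$adjusted_p) &
      out$abs_corr >= corr_cut & out$vip > vip_cut & out$adjusted_p < alpha
  } else {
    out$selected <- out$abs_corr >= corr_cut & out$vip > vip_cut
  }
  out[order(-out$abs_corr), , drop = FALSE]
}
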