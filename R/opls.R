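# Two-class OPLS-DA: orthogonal-signal-corrected PLS with a single
# predictive component (Trygg-Wold style NIPALS for a univariate response).

# internal fast path, no validation: X centered matrix, y centered numeric
# vector, k orthogonal components. Returns the decomposition pieces needed
# for statistics and prediction.
.opls_core <- function(X, y, k) {
  p <- ncol(X)
  W_o <- matrix(0, p, k)
  P_o <- matrix(0, p, k)
  T_o <- matrix(0, nrow(X), k)
  Xd <- X
  for (j in seq_len(k)) {
    w <- drop(crossprod(Xd, y))
    w <- w / sqrt(sum(w * w))
    t <- drop(Xd %*% w)
    pl <- drop(crossprod(Xd, t)) / sum(t * t)
    wo <- pl - drop(crossprod(w, pl)) * w
    nwo <- sqrt(sum(wo * wo))
    if (nwo < 1e-12) {  # no class-orthogonal variation left
      W_o <- W_o[, seq_len(j - 1L), drop = FALSE]
      P_o <- P_o[, seq_len(j - 1L), drop = FALSE]
      T_o <- T_o[, seq_len(j - 1L), drop = FALSE]
      k <- j - 1L
      break
    }
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to * to)
    Xd <- Xd - tcrossprod(to, po)
    W_o[, j] <- wo
    P_o[, j] <- po
    T_o[, j] <- to
  }
  w <- drop(crossprod(Xd, y))
  nw <- sqrt(sum(w * w))
  if (nw < 1e-15) stop("response carries no covariance with the predictors")
  w <- w / nw
  t_p <- drop(Xd %*% w)
  p_p <- drop(crossprod(Xd, t_p)) / sum(t_p * t_p)
  c_y <- sum(y * t_p) / sum(t_p * t_p)
  list(w = w, t_p = t_p, p_p = p_p, c_y = c_y,
       W_o = W_o, P_o = P_o, T_o = T_o, Xd = Xd, k = k)
}

# remove the orthogonal variation from new (scaled) data and return the
# predictive score
.opls_project <- function(w, W_o, P_o, Xnew) {
  Xnew <- as.matrix(Xnew)
  for (j in seq_len(ncol(W_o))) {
    to <- drop(Xnew %*% W_o[, j])
    Xnew <- Xnew - tcrossprod(to, P_o[, j])
  }
  drop(Xnew %*% w)
}

# -1/+1 encoding on alphabetically sorted classes; second class positive
.encode_classes <- function(labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("exactly two classes are required, got ",
         length(classes), ": ", paste(classes, collapse = ", "))
  y <- ifelse(labels == classes[2L], 1, -1)
  list(classes = classes, y = y)
}

#' Fit a two-class OPLS-DA model
#'
#' Iteratively extracts `n_orthogonal` components of predictor variation
#' orthogonal to the class vector, deflates them from `X`, then fits a
#' single predictive PLS component on the deflated matrix. The class is
#' encoded -1/+1 (alphabetical order) and centered; the predictive score
#' sign is fixed so the alphabetically second class has positive mean
#' score.
#'
#' @param X Column-centered (optionally scaled) samples x variables matrix.
#' @param labels Two-class vector parallel to the rows of `X`, each class
#'   with at least 3 samples.
#' @param n_orthogonal Number of orthogonal components; must be smaller
#'   than the rank of `X`.
#' @return An object of class `opls_model` with predictive scores/
#'   weights/loadings, orthogonal scores/loadings, and the fit statistics
#'   `r2x` (partitioned into predictive and orthogonal parts) and `r2y`.
#'   `q2` is `NA` until filled in by [cross_validate()].
#' @seealso [cross_validate()], [permutation_validation()], [splot()],
#'   [vip()]
#' @export
fit_opls_da <- function(X, labels, n_orthogonal = 0L) {
  X <- as.matrix(X)
  enc <- .encode_classes(labels)
  tab <- table(labels)
  if (any(tab < 3L))
    stop("each class needs at least 3 samples (class '",
         names(tab)[which.min(tab)], "' has ", min(tab), ")")
  if (nrow(X) != length(labels))
    stop("row count of X must equal the number of labels")
  n_orthogonal <- as.integer(n_orthogonal)
  if (n_orthogonal < 0L) stop("'n_orthogonal' must be non-negative")
  rk <- qr(X)$rank
  if (n_orthogonal >= rk)
    stop("'n_orthogonal' (", n_orthogonal, ") must be below rank(X) = ", rk)
  cm <- colMeans(X)
  if (max(abs(cm)) > 1e-6 * max(1, max(abs(X))))
    warning("X does not look column-centered; center (and scale) it first")

  y <- enc$y - mean(enc$y)
  fit <- .opls_core(X, y, n_orthogonal)

  # sign convention: positive mean predictive score for the second class
  if (mean(fit$t_p[labels == enc$classes[2L]]) < 0) {
    fit$w <- -fit$w; fit$t_p <- -fit$t_p
    fit$p_p <- -fit$p_p; fit$c_y <- -fit$c_y
  }

  ss_tot <- sum(X * X)
  ss_pred <- sum(fit$t_p^2) * sum(fit$p_p^2)
  ss_orth <- if (fit$k) sum(vapply(seq_len(fit$k), function(j)
    sum(fit$T_o[, j]^2) * sum(fit$P_o[, j]^2), 0)) else 0
  r2y <- 1 - sum((y - fit$t_p * fit$c_y)^2) / sum(y * y)

  vn <- colnames(X)
  if (is.null(vn)) vn <- paste0("V", seq_len(ncol(X)))
  structure(list(
    weights = setNames(fit$w, vn),
    predictive_scores = setNames(fit$t_p, rownames(X)),
    predictive_loadings = setNames(fit$p_p, vn),
    y_loading = fit$c_y,
    orthogonal_weights = fit$W_o,
    orthogonal_loadings = fit$P_o,
    orthogonal_scores = fit$T_o,
    n_orthogonal = fit$k,
    r2x = (ss_pred + ss_orth) / ss_tot,
    r2x_predictive = ss_pred / ss_tot,
    r2x_orthogonal = ss_orth / ss_tot,
    r2y = r2y,
    q2 = NA_real_,
    classes = enc$classes,
    positive_class = enc$classes[2L],
    labels = as.character(labels),
    y_centered = y,
    variable_names = vn,
    column_statistics = list(center = attr(X, "col_center"),
                             scale = attr(X, "col_scale"),
                             method = attr(X, "scaling_method"))),
    class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA model: %s vs %s (positive class: %s)\n",
              x$classes[1L], x$classes[2L], x$positive_class))
  cat(sprintf("  1 predictive + %d orthogonal component(s), %d variables\n",
              x$n_orthogonal, length(x$weights)))
  cat(sprintf("  R2X = %.3f (pred %.3f, orth %.3f)  R2Y = %.3f  Q2 = %s\n",
              x$r2x, x$r2x_predictive, x$r2x_orthogonal, x$r2y,
              ifelse(is.na(x$q2), "NA", sprintf("%.3f", x$q2))))
  invisible(x)
}

#' Predict scores and classes for new samples
#'
#' @param object An `opls_model`.
#' @param newdata Samples x variables matrix on the same scale as the
#'   training matrix (if the model stores scaling statistics they are
#'   applied first).
#' @param ... Unused.
#' @return A list with `t_p` (predictive scores), `y_hat` (continuous
#'   prediction on the centered -1/+1 scale) and `class`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cs <- object$column_statistics
  if (!is.null(cs$center)) {
    if (!is.null(colnames(newdata)))
      newdata <- newdata[, object$variable_names, drop = FALSE]
    newdata <- sweep(sweep(newdata, 2L, cs$center, "-"), 2L, cs$scale, "/")
  }
  t_new <- .opls_project(object$weights, object$orthogonal_weights,
                         object$orthogonal_loadings, newdata)
  y_hat <- t_new * object$y_loading
  cls <- ifelse(y_hat >= 0, object$classes[2L], object$classes[1L])
  list(t_p = t_new, y_hat = y_hat, class = cls)
}

# stratified fold assignment: within each class, shuffled round-robin
.stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# scale X according to method, returning matrix with stats attributes
.scale_by_method <- function(X, method) {
  if (method == "none") {
    out <- as.matrix(X)
    attr(out, "col_center") <- rep(0, ncol(out))
    attr(out, "col_scale") <- rep(1, ncol(out))
    attr(out, "scaling_method") <- "none"
    return(out)
  }
  scale_columns(X, method)
}

# cross-validated Q2 for a fixed number of orthogonal components.
# X is raw (unscaled); scaling statistics are re-estimated inside each
# training fold so no information leaks into the held-out samples.
.cv_q2 <- function(X, y_pm1, labels, folds, k, scaling, fold_id = NULL) {
  if (is.null(fold_id)) fold_id <- .stratified_folds(labels, folds)
  folds <- max(fold_id)
  press <- 0; tss <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (!any(test)) next
    if (length(unique(labels[!test])) < 2L)
      stop("fold ", f, " leaves a training class empty; reduce 'folds'")
    Xtr <- suppressWarnings(.scale_by_method(X[!test, , drop = FALSE],
                                             scaling))
    ytr <- y_pm1[!test]
    ybar <- mean(ytr)
    fit <- .opls_core(Xtr, ytr - ybar, k)
    Xte <- apply_scaling(X[test, , drop = FALSE], Xtr)
    t_new <- .opls_project(fit$w, fit$W_o, fit$P_o, Xte)
    y_hat <- ybar + t_new * fit$c_y
    press <- press + sum((y_pm1[test] - y_hat)^2)
    tss <- tss + sum((y_pm1[test] - ybar)^2)
  }
  1 - press / tss
}

#' Choose the number of orthogonal components by cross-validated Q2
#'
#' Stratified k-fold cross-validation on the raw (unscaled) matrix:
#' scaling statistics are re-estimated inside every training fold, the
#' held-out samples are projected with the training statistics, and
#' `Q2 = 1 - PRESS/TSS` is accumulated over folds for each candidate
#' component count. The chosen model is the smallest `n_orthogonal` whose
#' Q2 lies within 0.01 of the maximum (parsimony rule).
#'
#' @param X Raw samples x variables matrix (not yet scaled).
#' @param labels Two-class vector.
#' @param folds Number of folds (default 7, the common SIMCA-style
#'   convention); must be at least 2 and leave both classes represented in
#'   every training fold.
#' @param max_orthogonal Largest candidate orthogonal component count.
#' @param scaling Scaling re-estimated per training fold: `"pareto"`
#'   (default), `"unit_variance"`, `"center"` or `"none"`.
#' @param seed Optional integer seed for the fold shuffling.
#' @param fold_id Optional explicit fold assignment (integer vector over
#'   samples); overrides the stratified shuffle, e.g. to keep technical
#'   replicates in one fold.
#' @return A list with `n_orthogonal` (chosen), `q2` (named vector of Q2
#'   per candidate), and `q2_chosen`.
#' @export
cross_validate <- function(X, labels, folds = 7L, max_orthogonal = 2L,
                           scaling = c("pareto", "unit_variance", "center",
                                       "none"),
                           seed = NULL, fold_id = NULL) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  enc <- .encode_classes(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("'folds' must be at least 2")
  if (folds > nrow(X)) stop("'folds' exceeds the number of samples")
  if (!is.null(fold_id) && length(fold_id) != nrow(X))
    stop("'fold_id' must assign every sample")
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  q2 <- vapply(0:max_orthogonal, function(k)
    .cv_q2(X, enc$y, labels, folds, k, scaling, fold_id), 0)
  names(q2) <- paste0("orth", 0:max_orthogonal)
  best <- max(q2)
  chosen <- (0:max_orthogonal)[which(q2 >= best - 0.01)[1L]]
  list(n_orthogonal = chosen, q2 = q2,
       q2_chosen = q2[[chosen + 1L]])
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model under randomly shuffled class labels and records, for
#' every permutation, the in-sample R2Y, the cross-validated Q2 and the
#' Pearson correlation between the permuted and the true class vector. A
#' sound model's observed R2Y/Q2 should exceed the permuted scatter, and
#' the OLS regression lines of R2Y and Q2 on the absolute label
#' correlation (fitted including the observed point at correlation 1)
#' should have low intercepts. Shuffles that reproduce the true labeling
#' are rejected and redrawn.
#'
#' @param X Raw samples x variables matrix (scaling is re-estimated per
#'   training fold, as in [cross_validate()]).
#' @param labels Two-class vector.
#' @param n_permutations Number of label shuffles (>= 1).
#' @param folds Cross-validation folds for Q2.
#' @param n_orthogonal Orthogonal component count used throughout.
#' @param scaling Per-fold scaling method.
#' @param seed Optional integer seed; fixes shuffles and fold splits.
#' @return An object of class `opls_permutation`: lists `permuted_r2y`,
#'   `permuted_q2`, `label_correlations`, the `observed_r2y`/`observed_q2`,
#'   and the regression intercepts `r2y_intercept`, `q2_intercept`.
#' @export
permutation_validation <- function(X, labels, n_permutations = 200L,
                                   folds = 7L, n_orthogonal = 0L,
                                   scaling = c("pareto", "unit_variance",
                                               "center", "none"),
                                   seed = NULL) {
  scaling <- match.arg(scaling)
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop("'n_permutations' must be at least 1")
  X <- as.matrix(X)
  labels <- as.character(labels)
  enc <- .encode_classes(labels)
  if (!is.null(seed)) set.seed(seed)

  Xs <- suppressWarnings(.scale_by_method(X, scaling))
  obs_fit <- fit_opls_da(Xs, labels, n_orthogonal)
  obs_r2y <- obs_fit$r2y
  obs_q2 <- .cv_q2(X, enc$y, labels, folds, n_orthogonal, scaling)

  r2y <- numeric(n_permutations)
  q2 <- numeric(n_permutations)
  rr <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    repeat {
      perm <- sample(labels)
      if (!identical(perm, labels)) break
    }
    yp <- ifelse(perm == enc$classes[2L], 1, -1)
    rr[i] <- cor(yp, enc$y)
    ypc <- yp - mean(yp)
    fit <- .opls_core(Xs, ypc, n_orthogonal)
    r2y[i] <- 1 - sum((ypc - fit$t_p * fit$c_y)^2) / sum(ypc^2)
    q2[i] <- .cv_q2(X, yp, perm, folds, n_orthogonal, scaling)
  }

  ar <- abs(c(1, rr))
  r2y_int <- unname(coef(lm(c(obs_r2y, r2y) ~ ar))[1L])
  q2_int <- unname(coef(lm(c(obs_q2, q2) ~ ar))[1L])

  structure(list(n_permutations = n_permutations,
                 permuted_r2y = r2y, permuted_q2 = q2,
                 label_correlations = rr,
                 observed_r2y = obs_r2y, observed_q2 = obs_q2,
                 r2y_intercept = r2y_int, q2_intercept = q2_int,
                 n_orthogonal = n_orthogonal, folds = folds,
                 scaling = scaling),
            class = "opls_permutation")
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf("Permutation validation (%d shuffles, %d-fold CV, %d orth)\n",
              x$n_permutations, x$folds, x$n_orthogonal))
  cat(sprintf("  observed R2Y = %.3f, Q2 = %.3f\n",
              x$observed_r2y, x$observed_q2))
  cat(sprintf("  permuted Q2: max = %.3f, empirical p = %.4f\n",
              max(x$permuted_q2),
              (1 + sum(x$permuted_q2 >= x$observed_q2)) /
                (1 + x$n_permutations)))
  cat(sprintf("  intercepts: R2Y %.3f, Q2 %.3f\n",
              x$r2y_intercept, x$q2_intercept))
  invisible(x)
}

#' Export a permutation scatter as delimited text
#'
#' Writes one row per permutation (plus the observed model) with columns
#' `label_correlation`, `r2y`, `q2` — the axes of the conventional
#' permutation validation plot.
#'
#' @param perm An `opls_permutation`.
#' @param path Output file path.
#' @export
write_permutation_scatter <- function(perm, path) {
  stopifnot(inherits(perm, "opls_permutation"))
  df <- data.frame(
    label_correlation = c(perm$label_correlations, 1),
    r2y = c(perm$permuted_r2y, perm$observed_r2y),
    q2 = c(perm$permuted_q2, perm$observed_q2),
    observed = c(rep(FALSE, perm$n_permutations), TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
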