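# Independent oracles used across the suite. Deliberately naive: textbook
# formulations, brute-force loops, no shared code with the package path.

# textbook NIPALS for one PLS component with a single response: iterate
# u -> w -> t -> c -> u until the score stabilizes
oracle_nipals_pls1 <- function(X, y, tol = 1e-12, max_iter = 500L) {
  u <- y
  t_old <- rep(0, nrow(X))
  for (i in seq_len(max_iter)) {
    w <- drop(crossprod(X, u)) / sum(u * u)
    w <- w / sqrt(sum(w * w))
    t <- drop(X %*% w)
    c_y <- sum(y * t) / sum(t * t)
    u <- y * c_y / (c_y * c_y)
    if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t * t))) break
    t_old <- t
  }
  p <- drop(crossprod(X, t)) / sum(t * t)
  list(w = w, t = t, p = p, c = c_y)
}

# brute-force BH step-up: for each p_i, the smallest capped m*p_(j)/j over
# all j with p_(j) >= p_i (double loop, no cummin tricks)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[o[i]] <- min(1, best)
  }
  adj
}

# point-by-point angular SUS region test from the stated definitions
oracle_sus_region <- function(ca, cb, va, vb, vip_cut = 1,
                              axis_angle = 15, diag_angle = 20,
                              floor = 0.3) {
  if (max(va, vb) <= vip_cut) return(NA_character_)
  if (abs(ca) < floor && abs(cb) < floor) return("unclassified")
  theta <- atan2(cb, ca) * 180 / pi
  line_dist <- function(phi) {
    d <- abs((theta - phi) %% 180)
    min(d, 180 - d)
  }
  if (line_dist(45) <= diag_angle) return("shared_positive")
  if (line_dist(-45) <= diag_angle) return("shared_negative")
  if (line_dist(0) <= axis_angle && abs(ca) >= floor) return("unique_a")
  if (line_dist(90) <= axis_angle && abs(cb) >= floor) return("unique_b")
  "unclassified"
}

# brute-force all-pairs correlation edge scan via cor.test
oracle_correlation_edges <- function(X, r_threshold, p_threshold) {
  m <- ncol(X)
  out <- NULL
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      ct <- cor.test(X[, i], X[, j])
      if (abs(ct$estimate) > r_threshold && ct$p.value < p_threshold)
        out <- rbind(out, data.frame(a = colnames(X)[i],
                                     b = colnames(X)[j],
                                     r = unname(ct$estimate)))
    }
  }
  out
}
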