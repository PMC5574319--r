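one_group_table <- function(seed, n = 8L, n_met = 6L, blocks = list()) {
  d <- study_design("G", n, met_names(n_met),
                    correlation_blocks = blocks, seed = seed)
  generate_metabolite_table(d)
}

test_that("perfectly correlated columns always form an edge", {
  tbl <- one_group_table(1)
  v <- tbl$values
  v[, 2L] <- 2 * v[, 1L]  # identical up to scale: r = 1
  tbl2 <- metabolite_table(tbl$sample_ids, tbl$group_labels, v)
  e <- correlation_edges(tbl2, "G", r_threshold = 0.95, p_threshold = 0.05)
  expect_true(any(e$metabolite_a == "met01" & e$metabolite_b == "met02"))
  expect_equal(e$r[e$metabolite_a == "met01" & e$metabolite_b == "met02"],
               1, tolerance = 1e-12)
})

test_that("r = 0.7 at n = 8 fails the p rule, matching the t-transform", {
  # closed form: t = r sqrt(n-2)/sqrt(1-r^2); at r = 0.7, n = 8 the
  # two-sided p is ~0.053 > 0.05, so the edge must be dropped
  r <- 0.7; n <- 8
  p_analytic <- 2 * pt(-abs(r * sqrt(n - 2) / sqrt(1 - r^2)), n - 2)
  expect_gt(p_analytic, 0.05)
  expect_lt(p_analytic, 0.056)
  # build a pair with sample correlation exactly 0.7 via Gram-Schmidt
  set.seed(2)
  a <- rnorm(n)
  b0 <- rnorm(n)
  a_c <- (a - mean(a)) / sd(a)
  b_r <- residuals(lm(b0 ~ a))
  b_r <- b_r / sd(b_r)
  b <- r * a_c + sqrt(1 - r^2) * b_r
  expect_equal(cor(a, b), r, tolerance = 1e-12)
  tbl <- metabolite_table(paste0("s", 1:n), rep("G", n),
                          cbind(metA = a - min(a), metB = b - min(b)))
  e <- correlation_edges(tbl, "G", r_threshold = 0.65, p_threshold = 0.05)
  expect_identical(nrow(e), 0L)
})

test_that("edge sets equal a brute-force cor.test scan on random tables", {
  for (s in 1:25) {
    tbl <- one_group_table(s, n = sample(6:12, 1), n_met = sample(4:8, 1))
    e <- correlation_edges(tbl, "G", r_threshold = 0.5, p_threshold = 0.1)
    or <- oracle_correlation_edges(tbl$values, 0.5, 0.1)
    if (is.null(or)) {
      expect_identical(nrow(e), 0L)
    } else {
      expect_identical(paste(e$metabolite_a, e$metabolite_b),
                       paste(or$a, or$b))
      expect_equal(e$r, or$r, tolerance = 1e-10)
    }
  }
})

test_that("edges are invariant under sample and metabolite reordering", {
  tbl <- one_group_table(7, n = 12L, n_met = 8L,
                         blocks = list(list(metabolites = met_names(8)[1:3],
                                            rho = 0.8)))
  e1 <- correlation_edges(tbl, "G", 0.5, 0.1)
  set.seed(1)
  rs <- sample(nrow(tbl$values)); cs <- sample(ncol(tbl$values))
  tbl2 <- metabolite_table(tbl$sample_ids[rs], tbl$group_labels[rs],
                           tbl$values[rs, cs])
  e2 <- correlation_edges(tbl2, "G", 0.5, 0.1)
  key <- function(e) sort(paste(pmin(e$metabolite_a, e$metabolite_b),
                                pmax(e$metabolite_a, e$metabolite_b)))
  expect_identical(key(e1), key(e2))
})

test_that("at n = 8 every |r| > 0.85 edge automatically passes p < 0.05", {
  # |r| must exceed ~0.707 for p < 0.05 at n = 8, so the brain threshold
  # subsumes the p rule; verified via the t-transform on many seeds
  r_crit <- sqrt(qt(0.025, 6)^2 / (qt(0.025, 6)^2 + 6))
  expect_equal(r_crit, 0.707, tolerance = 0.001)
  for (s in 1:20) {
    tbl <- one_group_table(s, n = 8L, n_met = 6L,
                           blocks = list(list(metabolites =
                                                met_names(6)[1:3],
                                              rho = 0.9)))
    e_r_only <- correlation_edges(tbl, "G", 0.85, 0.999999)
    e_both <- correlation_edges(tbl, "G", 0.85, 0.05)
    expect_identical(e_r_only[c("metabolite_a", "metabolite_b")],
                     e_both[c("metabolite_a", "metabolite_b")])
  }
})

test_that("constant metabolites are excluded with a warning, not an error", {
  tbl <- one_group_table(3)
  v <- tbl$values
  v[, 4L] <- 5
  tbl2 <- metabolite_table(tbl$sample_ids, tbl$group_labels, v)
  expect_warning(e <- correlation_edges(tbl2, "G", 0.5, 0.1), "constant")
  expect_false(any(c(e$metabolite_a, e$metabolite_b) == "met04"))
  expect_error(correlation_edges(tbl, "nope", 0.5, 0.1), "not present")
  expect_error(correlation_edges(tbl, "G", 1.5, 0.05), "\\(0, 1\\)")
})

test_that("node directions flag planted shifts and flip under group swap", {
  d <- planted_design(1, n_met = 6L, n_markers = 2L)  # met01 up in M
  tbl <- generate_metabolite_table(d)
  dir1 <- node_directions(tbl, "M", "NC")
  dir2 <- node_directions(tbl, "NC", "M")
  flip <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(flip[dir1]), unname(dir2))
  # identical groups: everything unchanged
  same <- metabolite_table(tbl$sample_ids, tbl$group_labels,
                           rbind(tbl$values[1:8, ], tbl$values[1:8, ]))
  expect_true(all(node_directions(same, "M", "NC") == "unchanged"))
  expect_error(node_directions(tbl, "M", "nope"), "not present")
  # planted +2 SD metabolite: analytic Welch power at n = 8 is 0.96, so
  # the detection rate should exceed 95% up to Monte-Carlo error
  power_analytic <- power.t.test(n = 8, delta = 2, sd = 1,
                                 sig.level = 0.05)$power
  expect_gte(power_analytic, 0.95)
  hits <- vapply(1:100, function(s) {
    t2 <- generate_metabolite_table(planted_design(s, n_met = 4L,
                                                   n_markers = 1L))
    node_directions(t2, "M", "NC")[["met01"]] == "up"
  }, TRUE)
  mc_se <- sqrt(power_analytic * (1 - power_analytic) / 100)
  expect_gte(mean(hits), power_analytic - 3 * mc_se)
})

test_that("structural edges reproduce the planted pairs and reject misuse", {
  S <- generate_similarity_matrix(met_names(5),
                                  list(c("met01", "met02")),
                                  high = 0.9, seed = 1)
  expect_identical(nrow(structural_edges(S, 1.0)), 0L)
  e <- structural_edges(S, 0.8)
  expect_identical(nrow(e), 1L)
  expect_identical(c(e$metabolite_a, e$metabolite_b), c("met01", "met02"))
  # brute-force upper-triangle scan on random matrices
  for (s in 1:20) {
    M <- generate_similarity_matrix(met_names(6), seed = s)
    thr <- runif(1, 0.05, 0.5)
    e2 <- structural_edges(M, thr)
    cnt <- sum(M[upper.tri(M)] >= thr)
    expect_identical(nrow(e2), cnt)
  }
  bad <- S; bad[1, 2] <- 0.1
  expect_error(structural_edges(bad, 0.5), "symmetric")
  expect_error(structural_edges(S, 0), "\\(0, 1\\]")
})

test_that("assembled networks keep kinds, attributes and counts", {
  tbl <- one_group_table(11, n = 10L, n_met = 5L,
                         blocks = list(list(metabolites =
                                              met_names(5)[1:2],
                                            rho = 0.95)))
  ce <- correlation_edges(tbl, "G", 0.6, 0.05)
  S <- generate_similarity_matrix(met_names(5),
                                  list(c("met01", "met02")), seed = 1)
  se <- structural_edges(S, 0.8)
  dirs <- setNames(rep("up", 5), met_names(5))
  g <- assemble_network(ce, se, dirs)
  expect_equal(igraph::ecount(g), nrow(ce) + nrow(se))
  expect_setequal(unique(igraph::E(g)$kind),
                  c("correlation", "structural"))
  # met01-met02 carries both a correlation and a structural edge
  pair_kinds <- igraph::E(g)[igraph::V(g)["met01"] %--%
                               igraph::V(g)["met02"]]$kind
  expect_setequal(pair_kinds, c("correlation", "structural"))
  expect_true(all(igraph::V(g)$direction == "up"))
  # empty input with drop_isolated gives the empty graph
  g0 <- assemble_network(NULL, NULL, dirs, drop_isolated = TRUE)
  expect_equal(igraph::vcount(g0), 0)
  g1 <- assemble_network(NULL, NULL, dirs, drop_isolated = FALSE)
  expect_equal(igraph::vcount(g1), 5)
})

test_that("planted correlation blocks are recovered through the thresholds", {
  # single-group block rho = 0.9, size 5, n = 30: a reduced version of the
  # acceptance property (10 seeds here)
  within <- 0; between <- 0; nw <- 0; nb <- 0
  for (s in 1:10) {
    tbl <- one_group_table(s, n = 30L, n_met = 12L,
                           blocks = list(list(metabolites =
                                                met_names(12)[1:5],
                                              rho = 0.9)))
    e <- correlation_edges(tbl, "G", 0.65, 0.05)
    blk <- met_names(12)[1:5]
    pairs <- t(combn(met_names(12), 2))
    inblk <- pairs[, 1] %in% blk & pairs[, 2] %in% blk
    key <- paste(e$metabolite_a, e$metabolite_b)
    hit <- paste(pairs[, 1], pairs[, 2]) %in% key
    within <- within + sum(hit[inblk]); nw <- nw + sum(inblk)
    between <- between + sum(hit[!inblk]); nb <- nb + sum(!inblk)
  }
  expect_gte(within / nw, 0.95)
  expect_lt(between / nb, 0.05)
})

test_that("network export writes GraphML and TSV side files", {
  tbl <- one_group_table(12, n = 10L, n_met = 4L)
  ce <- correlation_edges(tbl, "G", 0.3, 0.5)
  g <- assemble_network(ce, NULL, NULL, drop_isolated = FALSE)
  gml <- withr::local_tempfile(fileext = ".graphml")
  etsv <- withr::local_tempfile(fileext = ".tsv")
  ntsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(g, gml, etsv, ntsv)
  expect_true(file.exists(gml))
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::ecount(reread), igraph::ecount(g))
  expect_identical(nrow(read.delim(etsv)), as.integer(igraph::ecount(g)))
})
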