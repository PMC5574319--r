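# Thresholded Pearson correlation networks with structural-similarity
# edges and up/down node direction, built per group.

#' Thresholded Pearson correlation edges within one group
#'
#' All-pairs Pearson correlations across the group's samples; two-sided
#' p-values from the t-distribution transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`. Pairs with `|r| > r_threshold`
#' and `p < p_threshold` are kept. The serum networks of the source domain
#' conventionally use `|r| > 0.65`, brain networks `|r| > 0.85`, both at
#' raw p < 0.05 (no multiplicity correction by default; set `bh = TRUE`
#' to screen on BH-adjusted p instead).
#'
#' @param table A `metabolite_table`.
#' @param group Group whose samples are correlated (>= 4 samples).
#' @param r_threshold,p_threshold Thresholds in (0, 1).
#' @param bh Adjust the pair p-values by Benjamini-Hochberg before
#'   thresholding (off by default).
#' @return A data.frame with columns `metabolite_a`, `metabolite_b`, `r`,
#'   `p`, `sign`, `kind = "correlation"`. Constant metabolites are
#'   excluded with a warning.
#' @export
correlation_edges <- function(table, group, r_threshold = 0.65,
                              p_threshold = 0.05, bh = FALSE) {
  stopifnot(inherits(table, "metabolite_table"))
  if (!group %in% table$group_labels)
    stop("group '", group, "' not present in the table")
  if (r_threshold <= 0 || r_threshold >= 1 ||
      p_threshold <= 0 || p_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  X <- table$values[table$group_labels == group, , drop = FALSE]
  n <- nrow(X)
  if (n < 4L) stop("group '", group, "' needs at least 4 samples")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warning("excluding constant metabolite(s) in group '", group, "': ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  m <- ncol(X)
  if (m < 2L)
    return(data.frame(metabolite_a = character(0),
                      metabolite_b = character(0), r = numeric(0),
                      p = numeric(0), sign = numeric(0),
                      kind = character(0)))
  C <- cor(X)
  iu <- which(upper.tri(C), arr.ind = TRUE)
  iu <- iu[order(iu[, 1L], iu[, 2L]), , drop = FALSE]  # row-major pairs
  r <- C[iu]
  r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_cl * sqrt(n - 2) / sqrt(1 - r_cl^2)
  p <- 2 * pt(-abs(tval), df = n - 2)
  if (bh) p <- bh_adjust(pmax(p, .Machine$double.xmin))
  keep <- abs(r) > r_threshold & p < p_threshold
  data.frame(metabolite_a = colnames(X)[iu[keep, 1L]],
             metabolite_b = colnames(X)[iu[keep, 2L]],
             r = r[keep], p = p[keep], sign = sign(r[keep]),
             kind = rep("correlation", sum(keep)))
}

#' Up/down/unchanged direction of each metabolite versus a reference group
#'
#' `up` if the group mean exceeds the reference mean with a two-sided
#' Welch p below `alpha`, `down` if it is lower, otherwise `unchanged`
#' (the conventional red/blue/neutral node coloring).
#'
#' @param table A `metabolite_table`.
#' @param group,reference_group Group names present in the table.
#' @param alpha Significance level for the raw t-test p.
#' @return Named character vector over metabolites with values `up`,
#'   `down`, `unchanged`.
#' @export
node_directions <- function(table, group, reference_group, alpha = 0.05) {
  stopifnot(inherits(table, "metabolite_table"))
  for (g in c(group, reference_group))
    if (!g %in% table$group_labels)
      stop("group '", g, "' not present in the table")
  A <- table$values[table$group_labels == group, , drop = FALSE]
  R <- table$values[table$group_labels == reference_group, , drop = FALSE]
  dir <- vapply(seq_len(ncol(A)), function(j) {
    p <- tryCatch(t.test(A[, j], R[, j])$p.value, error = function(e) 1)
    if (is.na(p) || p >= alpha) return("unchanged")
    if (mean(A[, j]) > mean(R[, j])) "up" else "down"
  }, "")
  setNames(dir, table$metabolite_names)
}

#' Structural-similarity edges above a threshold
#'
#' Connects metabolite pairs whose structural similarity meets the
#' threshold — the dotted edges flagging candidate substrate-product
#' relationships.
#'
#' @param similarity Symmetric numeric matrix with metabolite dimnames.
#' @param threshold Similarity cut in (0, 1].
#' @return A data.frame with columns `metabolite_a`, `metabolite_b`,
#'   `similarity`, `kind = "structural"`.
#' @export
structural_edges <- function(similarity, threshold = 0.8) {
  similarity <- as.matrix(similarity)
  if (!isSymmetric(unname(similarity), tol = 1e-8))
    stop("similarity matrix must be symmetric")
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  iu <- which(upper.tri(similarity), arr.ind = TRUE)
  iu <- iu[order(iu[, 1L], iu[, 2L]), , drop = FALSE]
  s <- similarity[iu]
  keep <- s >= threshold
  data.frame(metabolite_a = rownames(similarity)[iu[keep, 1L]],
             metabolite_b = colnames(similarity)[iu[keep, 2L]],
             similarity = s[keep],
             kind = rep("structural", sum(keep)))
}

#' Assemble a metabolite network graph
#'
#' Merges correlation and structural edge lists into one igraph multigraph
#' (a pair may carry one edge of each kind) with node `direction`
#' attributes from [node_directions()].
#'
#' @param cor_edges Data.frame from [correlation_edges()] (or `NULL`).
#' @param struct_edges Data.frame from [structural_edges()] (or `NULL`).
#' @param directions Named character vector from [node_directions()] (or
#'   `NULL`; nodes then get direction `"unchanged"`).
#' @param drop_isolated Drop metabolites without any edge.
#' @return An `igraph` object with edge attributes `kind`, `r`, `p`,
#'   `sign`, `similarity` and vertex attribute `direction`.
#' @export
assemble_network <- function(cor_edges = NULL, struct_edges = NULL,
                             directions = NULL, drop_isolated = TRUE) {
  blank <- data.frame(metabolite_a = character(0),
                      metabolite_b = character(0))
  ce <- if (is.null(cor_edges)) blank else cor_edges
  se <- if (is.null(struct_edges)) blank else struct_edges
  edges <- data.frame(
    from = c(ce$metabolite_a, se$metabolite_a),
    to = c(ce$metabolite_b, se$metabolite_b),
    kind = c(rep("correlation", nrow(ce)), rep("structural", nrow(se))),
    r = c(if (nrow(ce)) ce$r else numeric(0), rep(NA_real_, nrow(se))),
    p = c(if (nrow(ce)) ce$p else numeric(0), rep(NA_real_, nrow(se))),
    sign = c(if (nrow(ce)) ce$sign else numeric(0),
             rep(NA_real_, nrow(se))),
    similarity = c(rep(NA_real_, nrow(ce)),
                   if (nrow(se)) se$similarity else numeric(0)))
  nodes <- unique(c(names(directions), edges$from, edges$to))
  if (drop_isolated) nodes <- intersect(nodes, c(edges$from, edges$to))
  vert <- data.frame(name = nodes,
                     direction = if (is.null(directions)) "unchanged"
                                 else unname(ifelse(nodes %in%
                                                      names(directions),
                                                    directions[nodes],
                                                    "unchanged")))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
}

#' Write a metabolite network to GraphML plus TSV edge and node lists
#'
#' @param graph An igraph object from [assemble_network()].
#' @param graphml_path,edges_path,nodes_path Output paths (any may be
#'   `NULL` to skip).
#' @export
write_network <- function(graph, graphml_path = NULL, edges_path = NULL,
                          nodes_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    names(el)[1:2] <- c("metabolite_a", "metabolite_b")
    write.table(el, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(nodes_path)) {
    nl <- igraph::as_data_frame(graph, what = "vertices")
    names(nl)[1L] <- "metabolite"
    write.table(nl, nodes_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(graph)
}
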