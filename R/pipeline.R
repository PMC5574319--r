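# End-to-end orchestration: simulate -> preprocess -> per-comparison
# OPLS-DA with permutation validation -> markers -> SUS -> networks,
# with a machine-readable manifest. All randomness flows from one root
# seed split per stage.

#' Default six-group synthetic study design
#'
#' Emulates a stroke-treatment metabolomics study: a sham group (NC,
#' the reference), a disease model group (M), and four treatment groups
#' (HD, Ber, Bai, Jas), n = 8 per group. The brain preset carries 42
#' metabolites, the serum preset 26. Ten planted markers are shifted by
#' two within-group SDs in M (alternating sign); each treatment restores
#' a subset of them halfway toward the reference while leaving the rest
#' at the full disease shift, which creates shared and treatment-unique
#' structure for the SUS stage. Two five-metabolite correlation blocks
#' (rho = 0.6) emulate pathway-driven covariation.
#'
#' @param tissue `"brain"` (42 metabolites) or `"serum"` (26).
#' @param n_per_group Samples per group (default 8).
#' @param marker_shift Standardized shift of the planted markers in M.
#' @param seed Integer seed.
#' @return A [study_design()]; the planted marker names are stored in
#'   `attr(, "true_markers")`.
#' @export
default_study_design <- function(tissue = c("brain", "serum"),
                                 n_per_group = 8L, marker_shift = 2,
                                 seed = 1L) {
  tissue <- match.arg(tissue)
  m <- if (tissue == "brain") 42L else 26L
  metabolites <- sprintf("met%02d", seq_len(m))
  markers <- metabolites[1:10]
  groups <- c("NC", "M", "HD", "Ber", "Bai", "Jas")
  signs <- rep(c(1, -1), length.out = 10L)

  # subsets each treatment restores halfway toward the reference
  restored <- list(HD = 1:10, Ber = 1:6, Bai = 3:8, Jas = 5:10)
  eff <- data.frame(metabolite = markers, group = "M",
                    shift = marker_shift * signs)
  for (g in names(restored)) {
    residual <- rep(1, 10L)           # fraction of the disease shift left
    residual[restored[[g]]] <- 0.5
    eff <- rbind(eff, data.frame(metabolite = markers, group = g,
                                 shift = marker_shift * signs * residual))
  }

  blocks <- list(list(metabolites = markers[1:5], rho = 0.6),
                 list(metabolites = metabolites[11:15], rho = 0.6))
  d <- study_design(groups, n_per_group, metabolites, effects = eff,
                    correlation_blocks = blocks, seed = seed)
  attr(d, "true_markers") <- markers
  attr(d, "tissue") <- tissue
  d
}

#' Default pipeline configuration
#'
#' Collects every tunable stage parameter with its documented default:
#' water exclusion window 4.7-5.1 ppm, 0.04 ppm bins, total-area
#' normalization, Pareto scaling, 7-fold cross-validation with up to 2
#' orthogonal components, 200 label permutations (the full-scale
#' validation convention is 2000; lower it or raise it via
#' `permutations`), VIP > 1 / |corr| >= 0.6 / adjusted p < 0.05 marker
#' cuts, 15/20 degree SUS axis/diagonal angles with a 0.3 correlation
#' floor, and |r| > 0.65 (serum) or 0.85 (brain) with raw p < 0.05
#' network thresholds.
#'
#' @param tissue `"brain"` or `"serum"`; sets the metabolite count and
#'   the network correlation threshold.
#' @param seed Root seed; every stage derives its own seed from it.
#' @param n_per_group,permutations,folds,max_orthogonal,scaling,
#'   bin_width,normalization_target,exclude,vip_cut,corr_cut,alpha,
#'   axis_angle_deg,diag_angle_deg,corr_floor,r_threshold,p_threshold,
#'   similarity_threshold Stage parameters; see the stage functions.
#' @param table_path,spectra_path,similarity_path Optional paths to
#'   user-supplied inputs; when given, the simulate stage is skipped for
#'   that artifact.
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(tissue = c("brain", "serum"),
                                    seed = 1L,
                                    n_per_group = 8L,
                                    permutations = 200L,
                                    folds = 7L,
                                    max_orthogonal = 2L,
                                    scaling = "pareto",
                                    bin_width = 0.04,
                                    normalization_target = 100,
                                    exclude = list(c(4.7, 5.1)),
                                    vip_cut = 1.0,
                                    corr_cut = 0.6,
                                    alpha = 0.05,
                                    axis_angle_deg = 15,
                                    diag_angle_deg = 20,
                                    corr_floor = 0.3,
                                    r_threshold = NULL,
                                    p_threshold = 0.05,
                                    similarity_threshold = 0.8,
                                    table_path = NULL,
                                    spectra_path = NULL,
                                    similarity_path = NULL) {
  tissue <- match.arg(tissue)
  if (is.null(r_threshold))
    r_threshold <- if (tissue == "brain") 0.85 else 0.65
  cfg <- list(tissue = tissue, seed = as.integer(seed),
              n_per_group = as.integer(n_per_group),
              permutations = as.integer(permutations),
              folds = as.integer(folds),
              max_orthogonal = as.integer(max_orthogonal),
              scaling = scaling, bin_width = bin_width,
              normalization_target = normalization_target,
              exclude = exclude, vip_cut = vip_cut, corr_cut = corr_cut,
              alpha = alpha, axis_angle_deg = axis_angle_deg,
              diag_angle_deg = diag_angle_deg, corr_floor = corr_floor,
              r_threshold = r_threshold, p_threshold = p_threshold,
              similarity_threshold = similarity_threshold,
              table_path = table_path, spectra_path = spectra_path,
              similarity_path = similarity_path)
  class(cfg) <- "pipeline_config"
  cfg
}

# 32-bit FNV-1a over a string; tiny stable config fingerprint
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor on the low 16 bits (bytes never touch the high half), then a
    # 32-bit modular multiply done in two halves to stay within 2^53
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# stage seeds derived from the root seed, all below 2^31
.stage_seed <- function(root, offset) (root + 7919L * offset) %% 2147483647L

# run a stage, rethrowing any failure with the stage name attached
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Serialize an OPLS-DA model to JSON
#'
#' @param model An `opls_model`.
#' @param path Output file path.
#' @export
write_opls_model <- function(model, path) {
  stopifnot(inherits(model, "opls_model"))
  out <- list(classes = model$classes,
              positive_class = model$positive_class,
              n_orthogonal = model$n_orthogonal,
              r2x = model$r2x, r2x_predictive = model$r2x_predictive,
              r2x_orthogonal = model$r2x_orthogonal,
              r2y = model$r2y, q2 = model$q2,
              predictive_scores = as.list(model$predictive_scores),
              weights = as.list(model$weights),
              predictive_loadings = as.list(model$predictive_loadings),
              y_loading = model$y_loading)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (skipped per artifact when user inputs are supplied)
#' -> spectral preprocessing -> one OPLS-DA comparison per non-reference
#' group against the disease model group M (NC vs M and each treatment vs
#' M), each with cross-validated component choice and permutation
#' validation on the preprocessed spectra -> metabolite-level models with
#' marker tables -> SUS classification of each treatment against HD with
#' shared reference M -> per-group correlation networks with structural
#' edges. Every artifact is written under `out_dir`, and a manifest
#' records the package version, seed, full configuration and its hash.
#'
#' @param config A [default_pipeline_config()] (or modified copy).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory artifacts (`design`,
#'   `table`, `spectra`, `processed`, `models`, `markers`, `sus`,
#'   `networks`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("models", "sus", "network"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  seed <- config$seed
  pth <- function(...) file.path(out_dir, ...)

  design <- NULL
  markers_true <- NULL
  tbl <- .stage("simulate", {
    if (!is.null(config$table_path)) {
      read_metabolite_table(config$table_path)
    } else {
      design <- default_study_design(config$tissue, config$n_per_group,
                                      seed = .stage_seed(seed, 1L))
      markers_true <- attr(design, "true_markers")
      generate_metabolite_table(design)
    }
  })
  write_metabolite_table(tbl, pth("metabolite_table.tsv"))
  if (!is.null(markers_true))
    jsonlite::write_json(markers_true, pth("ground_truth_markers.json"))

  spectra <- .stage("simulate", {
    if (!is.null(config$spectra_path)) {
      read_binned_spectra(config$spectra_path)
    } else {
      sp <- random_peak_library(tbl$metabolite_names,
                                seed = .stage_seed(seed, 2L))
      render_binned_spectra(tbl, sp, bin_width = config$bin_width,
                            seed = .stage_seed(seed, 3L))
    }
  })
  write_binned_spectra(spectra, pth("binned_spectra.tsv"))

  sim <- .stage("simulate", {
    if (!is.null(config$similarity_path)) {
      read_similarity_matrix(config$similarity_path)
    } else {
      mk <- if (is.null(markers_true)) tbl$metabolite_names[1:10]
            else markers_true
      pairs <- lapply(seq(1L, 9L, by = 2L),
                      function(i) mk[c(i, i + 1L)])
      generate_similarity_matrix(tbl$metabolite_names, pairs,
                                 seed = .stage_seed(seed, 4L))
    }
  })
  write_similarity_matrix(sim, pth("similarity_matrix.tsv"))

  processed <- .stage("preprocess", {
    s <- exclude_regions(spectra, config$exclude)
    normalize_total_area(s, config$normalization_target)
  })
  write_binned_spectra(processed, pth("processed_spectra.tsv"))

  groups <- unique(tbl$group_labels)
  ref <- "M"
  if (!ref %in% groups)
    stop("pipeline expects a disease model group named 'M'")
  comparisons <- setdiff(groups, ref)

  models <- list()
  marker_tables <- list()
  met_models <- list()
  met_centered <- list()
  for (i in seq_along(comparisons)) {
    g <- comparisons[i]
    cmp <- paste0(g, "_vs_", ref)
    .stage(paste0("fit:", cmp), {
      keep <- processed$group_labels %in% c(g, ref)
      Xb <- processed$intensities[keep, , drop = FALSE]
      lb <- processed$group_labels[keep]
      cv <- cross_validate(Xb, lb, folds = config$folds,
                           max_orthogonal = config$max_orthogonal,
                           scaling = config$scaling,
                           seed = .stage_seed(seed, 10L + i))
      Xbs <- suppressWarnings(.scale_by_method(Xb, config$scaling))
      mod <- fit_opls_da(Xbs, lb, cv$n_orthogonal)
      mod$q2 <- cv$q2_chosen
      models[[cmp]] <- mod
      write_opls_model(mod, pth("models", paste0(cmp, "_model.json")))
      perm <- permutation_validation(
        Xb, lb, n_permutations = config$permutations,
        folds = config$folds, n_orthogonal = cv$n_orthogonal,
        scaling = config$scaling, seed = .stage_seed(seed, 30L + i))
      write_permutation_scatter(perm,
        pth("models", paste0(cmp, "_permutations.tsv")))
    })
    .stage(paste0("markers:", cmp), {
      keep <- tbl$group_labels %in% c(g, ref)
      Xm <- tbl$values[keep, , drop = FALSE]
      lb <- tbl$group_labels[keep]
      cv <- cross_validate(Xm, lb, folds = config$folds,
                           max_orthogonal = config$max_orthogonal,
                           scaling = config$scaling,
                           seed = .stage_seed(seed, 50L + i))
      Xms <- suppressWarnings(.scale_by_method(Xm, config$scaling))
      mod <- fit_opls_da(Xms, lb, cv$n_orthogonal)
      mod$q2 <- cv$q2_chosen
      met_models[[cmp]] <- mod
      met_centered[[cmp]] <- scale_columns(Xm, "center")
      fc <- fold_change_table(tbl, g, ref)
      marker_tables[[cmp]] <- marker_table(
        mod, met_centered[[cmp]], fc, corr_cut = config$corr_cut,
        vip_cut = config$vip_cut, alpha = config$alpha)
      write.table(marker_tables[[cmp]],
                  pth("models", paste0(cmp, "_markers.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  sus_results <- list()
  sus_partners <- intersect(c("Ber", "Bai", "Jas"), comparisons)
  if ("HD" %in% comparisons && length(sus_partners)) {
    mod_a <- met_models[[paste0("HD_vs_", ref)]]
    X_a <- met_centered[[paste0("HD_vs_", ref)]]
    for (g in sus_partners) {
      pair <- paste0("HD_", g)
      .stage(paste0("sus:", pair), {
        cmp <- paste0(g, "_vs_", ref)
        pts <- sus_profiles(mod_a, met_models[[cmp]], X_a,
                            met_centered[[cmp]], reference = ref)
        cls <- classify_shared_unique(
          pts, vip_cut = config$vip_cut,
          axis_angle_deg = config$axis_angle_deg,
          diag_angle_deg = config$diag_angle_deg,
          corr_floor = config$corr_floor)
        vc <- venn_counts(cls)
        sus_results[[pair]] <- list(points = pts, classification = cls,
                                     venn = vc)
        write_sus_table(pts, cls, pth("sus", paste0(pair, "_sus.tsv")))
        jsonlite::write_json(
          list(counts = as.list(vc$counts), members = vc$members),
          pth("sus", paste0(pair, "_venn.json")), auto_unbox = TRUE)
      })
    }
  }

  networks <- list()
  for (g in groups) {
    .stage(paste0("network:", g), {
      ce <- correlation_edges(tbl, g, r_threshold = config$r_threshold,
                              p_threshold = config$p_threshold)
      se <- structural_edges(sim, config$similarity_threshold)
      dir_ref <- if (g %in% c("NC", ref)) c("M", "NC") else c(g, ref)
      dirs <- node_directions(tbl, dir_ref[1L], dir_ref[2L],
                              alpha = config$alpha)
      nw <- assemble_network(ce, se, dirs)
      networks[[g]] <- nw
      write_network(nw, pth("network", paste0(g, "_network.graphml")),
                    pth("network", paste0(g, "_edges.tsv")),
                    pth("network", paste0(g, "_nodes.tsv")))
    })
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  manifest <- list(package = "oplsmet",
                   version = as.character(packageVersion("oplsmet")),
                   seed = seed,
                   config = unclass(config),
                   config_hash = .fnv1a(as.character(cfg_json)),
                   comparisons = paste0(comparisons, "_vs_", ref),
                   n_samples = length(tbl$sample_ids),
                   n_metabolites = length(tbl$metabolite_names),
                   n_bins = length(processed$bin_centers))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(design = design, table = tbl, spectra = spectra,
                 similarity = sim, processed = processed,
                 models = models, metabolite_models = met_models,
                 markers = marker_tables, sus = sus_results,
                 networks = networks, manifest = manifest))
}
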