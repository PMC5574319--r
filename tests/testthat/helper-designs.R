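# Shared fixture builders. All fixtures are generated in code at test time.

met_names <- function(m) sprintf("met%02d", seq_len(m))

# two-group design with `n_markers` metabolites shifted by `d` in group M
planted_design <- function(seed, n_per_group = 8L, n_met = 42L,
                           n_markers = 10L, d = 2,
                           groups = c("NC", "M"), blocks = list()) {
  mets <- met_names(n_met)
  eff <- data.frame(metabolite = mets[seq_len(n_markers)], group = "M",
                    shift = d * rep(c(1, -1), length.out = n_markers))
  study_design(groups, n_per_group, mets, eff,
               correlation_blocks = blocks, seed = seed)
}

null_design <- function(seed, n_per_group = 8L, n_met = 42L,
                        groups = c("NC", "M")) {
  study_design(groups, n_per_group, met_names(n_met), seed = seed)
}

# subset a metabolite table to two groups, returning matrix + labels
two_group_matrix <- function(tbl, a, b) {
  keep <- tbl$group_labels %in% c(a, b)
  list(X = tbl$values[keep, , drop = FALSE],
       labels = tbl$group_labels[keep])
}

# small deterministic spectra setup: one metabolite, one peak
single_peak_setup <- function(values = c(1, 2), center = 3, amp = 1.5,
                              hwhm = 0.01, baseline_sd = 0) {
  tbl <- metabolite_table(paste0("s", seq_along(values)),
                          rep("G", length(values)),
                          matrix(values, ncol = 1,
                                 dimnames = list(NULL, "metA")))
  sp <- spectral_params(ppm_range = c(0.5, 9.5), points = 8192L,
                        peaks = list(metA = data.frame(center = center,
                                                       amplitude = amp,
                                                       hwhm = hwhm)),
                        baseline_sd = baseline_sd)
  list(table = tbl, sp = sp)
}
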