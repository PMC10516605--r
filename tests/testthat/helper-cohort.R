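# Cohort builders shared by the calling and acceptance tests.

tiny_panel <- function(seed = 11L) {
  make_locus_panel(data.frame(
    locus_id = c("locA", "locB", "locC"),
    repeat_unit = c("A", "T", "G"),
    wt_repeat_count = c(20L, 12L, 8L)), seed = seed)
}

# n_controls WT controls plus n_tumors samples; tumors carry planted -1
# indels at `planted_loci` (in the first n_planted of them) at `vaf`.
make_cohort_specs <- function(panel, seed, n_controls = 8L, n_tumors = 10L,
                              n_planted = 0L, planted_loci = character(0),
                              vaf = 0.3, depth = 2000L, stutter_rate = 0.02,
                              stutter_decay = 0.3) {
  specs <- list()
  sheet <- list()
  add <- function(sid, group, planted) {
    specs[[sid]] <<- sample_spec(sid, group = group, depth = depth,
                                 planted_indels = planted,
                                 stutter_rate = stutter_rate,
                                 stutter_decay = stutter_decay,
                                 subst_error_rate = 0,
                                 seed = derive_test_seed(seed, sid))
    sheet[[sid]] <<- data.frame(sample_id = sid, group = group)
  }
  for (i in seq_len(n_controls))
    add(sprintf("wt_%02d", i), "wt_control", list())
  for (i in seq_len(n_tumors)) {
    planted <- list()
    if (i <= n_planted) {
      for (lid in planted_loci) planted[[lid]] <- list(offset = -1L,
                                                       vaf = vaf)
    }
    add(sprintf("tu_%02d", i), "tumor", planted)
  }
  list(specs = specs,
       sheet = do.call(rbind, c(sheet, list(make.row.names = FALSE))))
}

derive_test_seed <- function(seed, key) {
  u <- utf8ToInt(key)
  as.integer((as.numeric(seed) * 7717 + sum(u * seq_along(u))) %% 2147483647)
}

# Count-level cohort -> indel count table.
cohort_counts <- function(panel, cohort) {
  sim <- simulate_cohort(panel, cohort$specs, level = "counts")
  tabulate_indels(sim$observations, panel)
}

# Synthetic 7-marker trace panel with planted instability for `unstable_idx`
# markers; returns traces plus truth.
make_trace_panel <- function(panel, unstable_idx, shifts, noise_sd = 0,
                             seed = 1L) {
  markers <- panel[vapply(panel, `[[`, FALSE, "is_msi_marker")]
  sample_traces <- list()
  control_traces <- list()
  for (i in seq_along(markers)) {
    loc <- markers[[i]]
    control_traces[[loc$locus_id]] <- simulate_electropherogram(
      loc, setNames(1, loc$product_size_wt), 0.02, 0.3, noise_sd,
      seed = seed * 1000L + i)
    fr <- if (i %in% unstable_idx) {
      setNames(c(0.7, 0.3),
               c(loc$product_size_wt - shifts[i], loc$product_size_wt))
    } else setNames(1, loc$product_size_wt)
    sample_traces[[loc$locus_id]] <- simulate_electropherogram(
      loc, fr, 0.02, 0.3, noise_sd, seed = seed * 2000L + i)
  }
  list(sample = sample_traces, control = control_traces)
}
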