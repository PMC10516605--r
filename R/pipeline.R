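#' Pipeline run configuration
#'
#' Bundles every threshold and seed the pipeline uses; each default equals
#' the corresponding stage default. Serialises to and from a single JSON
#' file.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param depth Reads per locus per sample.
#' @param stutter_rate,stutter_decay,subst_error_rate Simulator noise model
#'   (see [sample_spec()]).
#' @param alpha FSM positivity threshold on BH-adjusted q-values.
#' @param min_frequency Hotspot reporting threshold (strict).
#' @param top_k Hotspot top-read count.
#' @param min_rel_height,min_separation_bp Peak-calling parameters.
#' @param tolerance_bp New-peak matching tolerance.
#' @param max_primer_mismatches,flank_anchor_len,max_flank_mismatches Read
#'   processing parameters.
#' @param floor_eps Zero-VAF floor (`NULL` = derive from control depth).
#' @param n_min_controls Minimum controls for a Weibull fit.
#' @param noise_sd Trace baseline noise (fraction of full peak height).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, depth = 2000L, stutter_rate = 0.02,
                       stutter_decay = 0.3, subst_error_rate = 0.001,
                       alpha = 0.05, min_frequency = 0.04, top_k = 300L,
                       min_rel_height = 0.10, min_separation_bp = 2L,
                       tolerance_bp = 0L, max_primer_mismatches = 2L,
                       flank_anchor_len = 6L, max_flank_mismatches = 0L,
                       floor_eps = NULL, n_min_controls = 5L,
                       noise_sd = 0.02) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Planted design of the bundled demonstration cohort
#'
#' The demo cohort mirrors a mouse MMR-deficient study design: 10
#' organoid-like tumours, 18 end-stage tumours, 16 tumour-matched mucosa
#' samples, and 8 wild-type controls, with -1 frameshifts planted at five
#' coding mononucleotide-repeat loci so that the per-group truth frequencies
#' reproduce a published cohort table (e.g. 17/18 = 94.4%). Denominators
#' smaller than the group (Nacad in organoids, Maz in end-stage tumours and
#' mucosa) are realised as amplicon dropout: those samples carry a depth
#' override of 0 at the locus.
#'
#' @return A nested list: per group, per locus, `n_positive` / `n_evaluable`.
#' @export
demo_cohort_plan <- function() {
  list(
    organoid = list(n = 10L, plant = list(
      Asxl1 = c(10L, 10L), Maz = c(2L, 10L), Xirp1 = c(10L, 10L),
      Senp6 = c(10L, 10L), Nacad = c(6L, 8L))),
    end_stage = list(n = 18L, plant = list(
      Asxl1 = c(17L, 18L), Maz = c(2L, 16L), Xirp1 = c(18L, 18L),
      Senp6 = c(17L, 18L), Nacad = c(17L, 18L))),
    mucosa = list(n = 16L, plant = list(
      Asxl1 = c(14L, 14L), Maz = c(1L, 14L), Xirp1 = c(16L, 16L),
      Senp6 = c(16L, 16L), Nacad = c(16L, 16L))),
    wt_control = list(n = 8L, plant = list())
  )
}

#' Build the demonstration cohort
#'
#' Expands [demo_cohort_plan()] into concrete [sample_spec()]s: within each
#' group the first `n_positive` samples carry the planted -1 indel (true VAF
#' drawn uniformly in 0.25-0.55 under the cohort seed) and samples beyond
#' `n_evaluable` get a depth-0 override (dropout) at that locus.
#'
#' @param config A [run_config()].
#' @param plan A cohort plan, by default [demo_cohort_plan()].
#' @return List with `specs` (list of `sample_spec`), `sample_sheet`
#'   (data frame `sample_id`, `group`), and `truth` (planted frequencies per
#'   locus and group).
#' @export
build_demo_cohort <- function(config, plan = demo_cohort_plan()) {
  specs <- list()
  sheet <- list()
  truth <- list()
  with_seed(derive_seed(config$seed, "cohort"), {
    for (grp in names(plan)) {
      g <- plan[[grp]]
      for (i in seq_len(g$n)) {
        sid <- sprintf("%s_%02d", grp, i)
        planted <- list()
        overrides <- integer(0)
        for (lid in names(g$plant)) {
          n_pos <- g$plant[[lid]][1]
          n_eval <- g$plant[[lid]][2]
          if (i > n_eval) {
            overrides[lid] <- 0L
          } else if (i <= n_pos) {
            planted[[lid]] <- list(offset = -1L,
                                   vaf = round(runif(1, 0.25, 0.55), 3))
          }
        }
        specs[[sid]] <- sample_spec(
          sid, group = grp, depth = config$depth,
          planted_indels = planted,
          stutter_rate = config$stutter_rate,
          stutter_decay = config$stutter_decay,
          subst_error_rate = config$subst_error_rate,
          depth_overrides = if (length(overrides)) overrides else NULL,
          seed = derive_seed(config$seed, sid))
        sheet[[sid]] <- data.frame(sample_id = sid, group = grp)
      }
      for (lid in names(g$plant)) {
        truth[[paste(grp, lid)]] <- data.frame(
          group = grp, locus_id = lid, offset = -1L,
          n_positive = g$plant[[lid]][1], n_evaluable = g$plant[[lid]][2],
          frequency = g$plant[[lid]][1] / g$plant[[lid]][2])
      }
    }
  })
  list(specs = specs,
       sample_sheet = do.call(rbind, c(sheet, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

# MSI fragment-analysis plan for the demo cohort: every organoid is MSI-H
# (all seven markers shifted); shifts are deletions of 1-12 bp drawn per
# sample under the cohort seed.
demo_msi_truth <- function(config, panel, organoid_ids) {
  markers <- names(panel)[vapply(panel, `[[`, FALSE, "is_msi_marker")]
  with_seed(derive_seed(config$seed, "msi"), {
    out <- lapply(organoid_ids, function(sid)
      setNames(sample(1:12, length(markers), replace = TRUE), markers))
    names(out) <- organoid_ids
    out
  })
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline on the demonstration cohort
#'
#' simulate -> count -> call -> msi -> hotspot, writing every table plus a
#' manifest with file checksums. The whole run is a pure function of the
#' configuration: identical config (and therefore seed) gives byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param plan Cohort plan (default [demo_cohort_plan()]).
#' @param level `"reads"` simulates, writes, and re-processes full reads for
#'   the coding loci; `"counts"` uses the count-level fast path.
#' @return Invisibly, a list with the per-stage objects (`counts`, `calls`,
#'   `frequency`, `frequency_table`, `msi_reports`, `hotspot`, `truth`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir, plan = demo_cohort_plan(),
                         level = c("reads", "counts")) {
  level <- match.arg(level)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- run_stage("panel", demo_panel())
  cohort <- run_stage("cohort", build_demo_cohort(config, plan))
  coding <- panel[!vapply(panel, `[[`, FALSE, "is_msi_marker")]
  class(coding) <- "repeat_panel"

  counts <- run_stage("count", {
    if (level == "reads") {
      obs <- list()
      for (spec in cohort$specs) {
        sim <- simulate_cohort(coding, list(spec), level = "reads")
        obs[[spec$sample_id]] <- count_sample(
          sim$reads[[spec$sample_id]], coding, spec$sample_id,
          config$max_primer_mismatches, config$flank_anchor_len,
          config$max_flank_mismatches)
      }
      tabulate_indels(do.call(rbind, c(obs, list(make.row.names = FALSE))),
                      coding)
    } else {
      sim <- simulate_cohort(coding, cohort$specs, level = "counts")
      tabulate_indels(sim$observations, coding)
    }
  })

  calls <- run_stage("call", call_positives(
    counts, cohort$sample_sheet, alpha = config$alpha,
    floor_eps = config$floor_eps, n_min = config$n_min_controls))
  freq <- run_stage("call", mutation_frequency(calls, cohort$sample_sheet))
  freq_table <- render_frequency_table(
    freq[freq$offset == -1L, , drop = FALSE],
    group_order = setdiff(names(plan), "wt_control"))

  msi <- run_stage("msi", {
    organoids <- cohort$sample_sheet$sample_id[
      cohort$sample_sheet$group == "organoid"]
    markers <- panel[vapply(panel, `[[`, FALSE, "is_msi_marker")]
    shifts <- demo_msi_truth(config, panel, organoids)
    control_traces <- lapply(markers, function(loc) simulate_electropherogram(
      loc, setNames(1, loc$product_size_wt), config$stutter_rate,
      config$stutter_decay, config$noise_sd,
      seed = derive_seed(config$seed, paste0("trace:wt:", loc$locus_id)),
      sample_id = "wt_control", marker_id = loc$locus_id))
    reports <- lapply(organoids, function(sid) {
      traces <- lapply(markers, function(loc) {
        sh <- shifts[[sid]][[loc$locus_id]]
        fr <- setNames(c(0.7, 0.3),
                       c(loc$product_size_wt - sh, loc$product_size_wt))
        simulate_electropherogram(
          loc, fr, config$stutter_rate, config$stutter_decay,
          config$noise_sd,
          seed = derive_seed(config$seed, paste0("trace:", sid, ":",
                                                 loc$locus_id)),
          sample_id = sid, marker_id = loc$locus_id)
      })
      score_msi_sample(traces, control_traces,
                       min_rel_height = config$min_rel_height,
                       min_separation_bp = config$min_separation_bp,
                       tolerance_bp = config$tolerance_bp,
                       sample_id = sid)
    })
    names(reports) <- organoids
    reports
  })

  hotspot <- run_stage("hotspot", {
    reference <- with_seed(derive_seed(config$seed, "hotspot-ref"),
                           random_dna(150))
    variants <- list(
      list(pos = 30L, ref = substr(reference, 30, 30),
           alt = setdiff(DNA_BASES, substr(reference, 30, 30))[1],
           freq = 0.40),
      list(pos = 75L, ref = substr(reference, 75, 75),
           alt = setdiff(DNA_BASES, substr(reference, 75, 75))[1],
           freq = 0.05),
      list(pos = 110L, ref = substr(reference, 110, 110),
           alt = setdiff(DNA_BASES, substr(reference, 110, 110))[1],
           freq = 0.03),
      list(pos = 130L, ref = substr(reference, 130, 130),
           alt = setdiff(DNA_BASES, substr(reference, 130, 130))[1],
           freq = 0.01))
    reads <- simulate_hotspot_reads(reference, variants,
                                    depth = config$depth,
                                    seed = derive_seed(config$seed,
                                                       "hotspot"))
    calls <- hotspot_call(reads, reference, K = config$top_k,
                          min_frequency = config$min_frequency,
                          locus_id = "Trp53_demo")
    list(reference = reference, variants = variants, calls = calls)
  })

  run_stage("report", {
    write_panel(panel, file.path(out_dir, "panel.fasta"),
                file.path(out_dir, "panel.json"))
    write_tsv_file(counts, file.path(out_dir, "counts.tsv"))
    write_tsv_file(calls, file.path(out_dir, "calls.tsv"))
    write_tsv_file(freq, file.path(out_dir, "frequency.tsv"))
    write_tsv_file(cohort$truth, file.path(out_dir, "truth_frequency.tsv"))
    msi_df <- do.call(rbind, lapply(msi, function(r) data.frame(
      sample_id = r$sample_id, n_evaluable = r$n_evaluable,
      n_unstable = r$n_unstable, classification = r$classification)))
    write_tsv_file(msi_df, file.path(out_dir, "msi_report.tsv"))
    hs <- hotspot$calls
    hs$supporting_ranks <- vapply(hs$supporting_ranks, paste, "",
                                  collapse = ",")
    write_tsv_file(hs, file.path(out_dir, "hotspot_calls.tsv"))
  })

  files <- c("panel.fasta", "panel.json", "counts.tsv", "calls.tsv",
             "frequency.tsv", "truth_frequency.tsv", "msi_report.tsv",
             "hotspot_calls.tsv")
  manifest <- list(
    package = "msifsm",
    version = as.character(utils::packageVersion("msifsm")),
    config = unclass(config),
    files = lapply(setNames(files, files), function(f)
      list(md5 = unname(md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(panel = panel, cohort = cohort, counts = counts,
                 calls = calls, frequency = freq,
                 frequency_table = freq_table, msi_reports = msi,
                 hotspot = hotspot, truth = cohort$truth,
                 manifest = manifest))
}

#' Render a publication-style frequency table
#'
#' Rows are `Gene(offset)`, columns are cohort groups, and cells are
#' percentages to one decimal (so a 20% cell prints as `20.0%`).
#'
#' @param frequency Output of [mutation_frequency()] (or the demo truth
#'   table with columns `locus_id`, `offset`, `group`, `frequency`).
#' @param group_order Optional column order.
#' @return A data frame of formatted percentages with row names
#'   `Gene(offset)` and a `footnote` attribute; printed with the footnote.
#' @export
render_frequency_table <- function(frequency, group_order = NULL) {
  if (!nrow(frequency)) stopf("frequency table is empty")
  frequency$label <- sprintf("%s(%d)", frequency$locus_id, frequency$offset)
  groups <- group_order %||% unique(frequency$group)
  groups <- intersect(groups, unique(frequency$group))
  labels <- unique(frequency$label)
  out <- data.frame(row.names = labels)
  for (g in groups) {
    sub <- frequency[frequency$group == g, , drop = FALSE]
    v <- setNames(sub$frequency, sub$label)[labels]
    out[[g]] <- ifelse(is.na(v), "", sprintf("%.1f%%", 100 * v))
  }
  attr(out, "footnote") <- "-1: deletion of one nucleotide in MNR region."
  class(out) <- c("fsm_frequency_table", "data.frame")
  out
}

#' @export
print.fsm_frequency_table <- function(x, ...) {
  print.data.frame(x, ...)
  cat(attr(x, "footnote"), "\n")
  invisible(x)
}
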