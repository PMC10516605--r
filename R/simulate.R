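#' Describe a simulated sample
#'
#' A `sample_spec` fixes everything the simulator needs for one sample: its
#' group label, sequencing depth per locus, planted somatic indels, and the
#' noise model. Noise has two parts: PCR stutter (a read's observed repeat
#' length slips with probability `stutter_rate`; the slip magnitude beyond 1
#' decays geometrically with `stutter_decay` and its sign is equiprobable)
#' and uniform substitution errors at `subst_error_rate` per base.
#'
#' @param sample_id Sample name.
#' @param group Group label; `"wt_control"` is reserved for wild-type
#'   controls, which may not carry planted indels.
#' @param depth Reads per locus (positive integer).
#' @param planted_indels Named list, one entry per locus:
#'   `list(offset = -1, vaf = 0.3)` plants a 1-unit deletion at true VAF 0.3.
#' @param stutter_rate Probability a read slips (in `[0, 1]`).
#' @param stutter_decay Geometric decay of slip magnitude (in `(0, 1)`).
#' @param subst_error_rate Per-base substitution error probability.
#' @param depth_overrides Optional named integer vector of per-locus depths;
#'   a value of 0 marks amplicon dropout (no coverage) at that locus.
#' @param seed Integer seed; all randomness for this sample flows from it.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, group = "tumor", depth = 2000L,
                        planted_indels = list(), stutter_rate = 0.02,
                        stutter_decay = 0.3, subst_error_rate = 0.001,
                        depth_overrides = NULL, seed = 1L) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1) stopf("depth must be a positive integer")
  if (stutter_rate < 0 || stutter_rate > 1)
    stopf("stutter_rate must be in [0, 1]")
  if (stutter_rate > 0 && (stutter_decay <= 0 || stutter_decay >= 1))
    stopf("stutter_decay must be in (0, 1)")
  if (subst_error_rate < 0 || subst_error_rate > 1)
    stopf("subst_error_rate must be in [0, 1]")
  if (length(planted_indels)) {
    if (is.null(names(planted_indels)) || any(!nzchar(names(planted_indels))))
      stopf("planted_indels must be a named list keyed by locus_id")
    for (pi in planted_indels) {
      if (is.null(pi$offset) || pi$offset == 0 ||
          pi$offset != round(pi$offset))
        stopf("planted offset must be a non-zero integer")
      if (is.null(pi$vaf) || pi$vaf < 0 || pi$vaf > 1)
        stopf("planted vaf must be in [0, 1]")
    }
  }
  if (identical(group, "wt_control") && length(planted_indels))
    stopf("wt_control samples may not carry planted indels")
  if (!is.null(depth_overrides)) {
    if (is.null(names(depth_overrides)))
      stopf("depth_overrides must be named by locus_id")
    if (any(depth_overrides < 0)) stopf("depths must be >= 0")
  }
  structure(list(sample_id = sample_id, group = group, depth = depth,
                 planted_indels = planted_indels,
                 stutter_rate = stutter_rate, stutter_decay = stutter_decay,
                 subst_error_rate = subst_error_rate,
                 depth_overrides = depth_overrides,
                 seed = as.integer(seed)),
            class = "sample_spec")
}

locus_depth <- function(spec, locus_id) {
  ov <- spec$depth_overrides
  if (!is.null(ov) && locus_id %in% names(ov)) as.integer(ov[[locus_id]])
  else spec$depth
}

# Signed stutter slip for n reads: 0 with prob 1 - rate, otherwise sign
# equiprobable and magnitude m >= 1 with P(m) proportional to decay^(m-1).
draw_slips <- function(n, rate, decay) {
  slip <- integer(n)
  if (rate <= 0 || n == 0) return(slip)
  hit <- runif(n) < rate
  nh <- sum(hit)
  if (nh > 0) {
    mag <- rgeom(nh, 1 - decay) + 1L
    sgn <- sample(c(-1L, 1L), nh, replace = TRUE)
    slip[hit] <- mag * sgn
  }
  slip
}

# Observed repeat counts for one (locus, sample); uses the current RNG
# stream. Truth: each read is mutant with probability vaf, then slips.
.sim_counts <- function(locus, spec) {
  d <- locus_depth(spec, locus$locus_id)
  if (d < 1) stopf("depth must be >= 1 for locus %s", locus$locus_id)
  wt <- locus$wt_repeat_count
  planted <- spec$planted_indels[[locus$locus_id]]
  true_count <- rep.int(wt, d)
  if (!is.null(planted)) {
    mut <- runif(d) < planted$vaf
    true_count[mut] <- wt + as.integer(planted$offset)
  }
  slip <- draw_slips(d, spec$stutter_rate, spec$stutter_decay)
  pmax(true_count + slip, 0L)
}

truth_rows <- function(spec) {
  if (!length(spec$planted_indels)) {
    return(data.frame(sample_id = character(0), locus_id = character(0),
                      offset = integer(0), true_vaf = numeric(0),
                      true_msi_unstable = logical(0)))
  }
  data.frame(
    sample_id = spec$sample_id,
    locus_id = names(spec$planted_indels),
    offset = vapply(spec$planted_indels, function(p) as.integer(p$offset), 0L),
    true_vaf = vapply(spec$planted_indels, function(p) as.numeric(p$vaf), 0),
    true_msi_unstable = TRUE,
    row.names = NULL
  )
}

#' Simulate observed repeat lengths for one locus
#'
#' Count-level fast path of the read simulator: returns only the per-read
#' observed repeat copy numbers (truth plus stutter slip), skipping sequence
#' construction. [simulate_reads()] draws its repeat counts from the same
#' derived seed, so both paths agree read for read.
#'
#' @param locus A [repeat_locus()].
#' @param spec A [sample_spec()].
#' @return Integer vector of observed repeat counts, one per read.
#' @export
simulate_repeat_counts <- function(locus, spec) {
  with_seed(derive_seed(spec$seed, locus$locus_id), .sim_counts(locus, spec))
}

# Mutate `n_err[i]` random positions of seqs[i], never inside the two
# protected anchor windows (protect bases of flank on each side of the
# repeat tract).
apply_subst_errors <- function(seqs, rate, locus, observed, protect = 6L) {
  if (rate <= 0) return(seqs)
  L <- nchar(seqs)
  nerr <- rbinom(length(seqs), L, rate)
  idx <- which(nerr > 0)
  if (!length(idx)) return(seqs)
  nf <- nchar(locus$fwd_primer)
  nl <- nchar(locus$left_flank)
  ulen <- nchar(locus$repeat_unit)
  for (i in idx) {
    tract_len <- observed[i] * ulen
    prot <- c(seq.int(nf + nl - protect + 1L, nf + nl),
              seq.int(nf + nl + tract_len + 1L, nf + nl + tract_len + protect))
    allowed <- setdiff(seq_len(L[i]), prot)
    if (!length(allowed)) next
    pos <- sample(allowed, min(nerr[i], length(allowed)))
    s <- seqs[i]
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(DNA_BASES, old), 1)
    }
    seqs[i] <- s
  }
  seqs
}

#' Simulate amplicon reads for one locus
#'
#' Each read spans the full amplicon:
#' `fwd_primer + left_flank + unit^observed + right_flank + rev_primer`,
#' where `observed` is the wild-type (or planted mutant) repeat count plus a
#' stutter slip. Substitution errors are applied everywhere except the
#' `protect` flank bases adjacent to the repeat tract on either side, so
#' flank anchoring stays testable independently of error handling (a stated
#' simplification).
#'
#' @inheritParams simulate_repeat_counts
#' @param protect Flank bases adjacent to the tract kept error-free.
#' @return A list with `reads` (character vector, named
#'   `sample:locus:serial`), `counts` (the true observed repeat counts), and
#'   `truth` (planted-indel rows for this sample).
#' @export
simulate_reads <- function(locus, spec, protect = 6L) {
  with_seed(derive_seed(spec$seed, locus$locus_id), {
    observed <- .sim_counts(locus, spec)
    seqs <- paste0(locus$fwd_primer, locus$left_flank,
                   strrep(locus$repeat_unit, observed),
                   locus$right_flank, locus$rev_primer)
    seqs <- apply_subst_errors(seqs, spec$subst_error_rate, locus, observed,
                               protect)
    names(seqs) <- sprintf("%s:%s:%06d", spec$sample_id, locus$locus_id,
                           seq_along(seqs))
    truth <- truth_rows(spec)
    list(reads = seqs, counts = observed,
         truth = truth[truth$locus_id == locus$locus_id, , drop = FALSE])
  })
}

#' Simulate a cohort
#'
#' Runs the simulator over every (sample, locus) pair, skipping loci with a
#' depth override of 0 (amplicon dropout).
#'
#' @param panel A `repeat_panel`.
#' @param specs List of [sample_spec()] objects.
#' @param level `"counts"` for the fast count-level path (observed repeat
#'   lengths only) or `"reads"` for full read sequences.
#' @return A list with `observations` (data frame `sample_id`, `locus_id`,
#'   `observed_repeat_count`, `usable`), `truth` (all planted-indel rows),
#'   and, at read level, `reads` (named list of per-sample read vectors).
#' @export
simulate_cohort <- function(panel, specs, level = c("counts", "reads")) {
  level <- match.arg(level)
  validate_panel(panel)
  obs <- list()
  reads <- list()
  truth <- list()
  for (spec in specs) {
    truth[[spec$sample_id]] <- truth_rows(spec)
    sample_reads <- character(0)
    for (locus in panel) {
      if (locus_depth(spec, locus$locus_id) == 0) next
      if (level == "counts") {
        counts <- simulate_repeat_counts(locus, spec)
      } else {
        sim <- simulate_reads(locus, spec)
        counts <- sim$counts
        sample_reads <- c(sample_reads, sim$reads)
      }
      obs[[length(obs) + 1L]] <- data.frame(
        sample_id = spec$sample_id, locus_id = locus$locus_id,
        observed_repeat_count = counts, usable = TRUE, row.names = NULL)
    }
    if (level == "reads") reads[[spec$sample_id]] <- sample_reads
  }
  out <- list(observations = do.call(rbind, obs),
              truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  if (level == "reads") out$reads <- reads
  out
}

#' Simulate a capillary-electrophoresis trace
#'
#' Each allele contributes its main peak plus a symmetric stutter ladder:
#' the peak at `k` bp from the allele has height
#' `fraction * stutter_rate * stutter_decay^(k-1)`. The trace is sampled on
#' a 1-bp grid spanning `product_size_wt +/- 15` bp, with optional additive
#' non-negative (half-normal) baseline noise.
#'
#' @param locus A [repeat_locus()]; fixes the grid centre.
#' @param allele_fractions Named numeric vector mapping fragment size in bp
#'   to allele fraction; fractions must sum to 1 (within 1e-6).
#' @param stutter_rate,stutter_decay Ladder parameters as in [sample_spec()].
#' @param noise_sd Scale of the half-normal baseline noise (same units as
#'   intensity; peak heights are allele fractions, so 0.02 is 2% of a
#'   full-height peak).
#' @param seed Seed for the noise draw.
#' @param sample_id,marker_id Labels attached to the trace.
#' @return An `electropherogram`: data frame with columns `size_bp`
#'   (1-bp grid) and `intensity`.
#' @export
simulate_electropherogram <- function(locus, allele_fractions,
                                      stutter_rate = 0.02,
                                      stutter_decay = 0.3, noise_sd = 0,
                                      seed = NULL, sample_id = NA_character_,
                                      marker_id = locus$locus_id) {
  if (is.null(names(allele_fractions)))
    stopf("allele_fractions must be named by fragment size in bp")
  if (abs(sum(allele_fractions) - 1) > 1e-6)
    stopf("allele fractions must sum to 1 (got %.8f)", sum(allele_fractions))
  sizes <- as.integer(names(allele_fractions))
  grid <- seq.int(locus$product_size_wt - 15L, locus$product_size_wt + 15L)
  intensity <- numeric(length(grid))
  add <- function(sz, h) {
    j <- match(sz, grid)
    if (!is.na(j)) intensity[j] <<- intensity[j] + h
  }
  for (i in seq_along(sizes)) {
    f <- allele_fractions[[i]]
    add(sizes[i], f)
    if (stutter_rate > 0) {
      k <- 1L
      repeat {
        h <- f * stutter_rate * stutter_decay^(k - 1)
        if (h < 1e-12 || k > 30L) break
        add(sizes[i] - k, h)
        add(sizes[i] + k, h)
        k <- k + 1L
      }
    }
  }
  if (noise_sd > 0)
    intensity <- intensity + with_seed(seed, abs(rnorm(length(grid), 0, noise_sd)))
  electropherogram(grid, intensity, sample_id = sample_id,
                   marker_id = marker_id)
}

#' Write simulation fixtures to disk
#'
#' Emits the panel (FASTA + JSON), one FASTQ per sample (constant Phred+33
#' quality), a TSV truth table, optional TSV traces, and a JSON manifest
#' listing every file with its MD5 checksum and the seeds used. Rerunning
#' with the same seeds reproduces every file byte for byte.
#'
#' @param panel A `repeat_panel`.
#' @param specs List of [sample_spec()] objects.
#' @param out_dir Output directory (created if needed).
#' @param traces Optional named list of `electropherogram` objects.
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return The manifest, invisibly.
#' @export
write_fixtures <- function(panel, specs, out_dir, traces = NULL,
                           overwrite = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stopf("manifest already exists at %s (use overwrite = TRUE)", manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  write_panel(panel, file.path(out_dir, "panel.fasta"),
              file.path(out_dir, "panel.json"))
  files <- c(files, "panel.fasta", "panel.json")
  truth <- list()
  for (spec in specs) {
    sim <- simulate_cohort(panel, list(spec), level = "reads")
    truth[[spec$sample_id]] <- sim$truth
    reads <- sim$reads[[spec$sample_id]]
    fq <- file.path(out_dir, paste0(spec$sample_id, ".fastq"))
    write_fastq(reads, fq)
    files <- c(files, basename(fq))
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  write_tsv_file(truth, file.path(out_dir, "truth.tsv"))
  files <- c(files, "truth.tsv")
  for (nm in names(traces)) {
    tp <- file.path(out_dir, paste0("trace_", nm, ".tsv"))
    write_tsv_file(as.data.frame(traces[[nm]])[c("size_bp", "intensity")], tp)
    files <- c(files, basename(tp))
  }
  manifest <- list(
    package = "msifsm",
    seeds = setNames(lapply(specs, `[[`, "seed"),
                     vapply(specs, `[[`, "", "sample_id")),
    files = lapply(setNames(files, files), function(f)
      list(md5 = unname(md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read / write FASTQ
#'
#' Thin wrappers over Biostrings I/O; written reads carry a constant quality
#' of "I" (Phred 40).
#'
#' @param reads Named character vector of read sequences.
#' @param path FASTQ path.
#' @return `write_fastq` returns `path` invisibly; `read_fastq` a named
#'   character vector.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::PhredQuality(strrep("I", nchar(reads)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, qual)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Simulate hotspot-amplicon reads
#'
#' Generates full-length copies of a reference amplicon in which each read
#' carries at most one planted variant, drawn with the requested frequencies;
#' uniform substitution errors are then applied.
#'
#' @param reference Reference amplicon sequence.
#' @param variants List of `list(pos, ref, alt, freq)` entries; `ref`/`alt`
#'   follow the edit-script conventions of [align_to_reference()]
#'   (substitution: both single bases; deletion: `alt = ""`; insertion:
#'   `ref = ""`, inserted before `pos`).
#' @param depth Number of reads.
#' @param subst_error_rate Per-base error probability.
#' @param seed Integer seed.
#' @return Character vector of reads.
#' @export
simulate_hotspot_reads <- function(reference, variants = list(),
                                   depth = 2000L, subst_error_rate = 0,
                                   seed = 1L) {
  if (!is_dna(reference)) stopf("reference must be a DNA string")
  freqs <- vapply(variants, function(v) as.numeric(v$freq), 0)
  if (sum(freqs) > 1) stopf("variant frequencies must sum to <= 1")
  haps <- c(vapply(variants, function(v)
    apply_edit(reference, v$pos, v$ref, v$alt), ""), reference)
  with_seed(seed, {
    which_hap <- sample.int(length(haps), depth, replace = TRUE,
                            prob = c(freqs, 1 - sum(freqs)))
    reads <- haps[which_hap]
    if (subst_error_rate > 0) {
      L <- nchar(reads)
      nerr <- rbinom(depth, L, subst_error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample(L[i], nerr[i])
        s <- reads[i]
        for (p in pos) {
          old <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(DNA_BASES, old), 1)
        }
        reads[i] <- s
      }
    }
    reads
  })
}

# Apply one edit to a sequence. Substitution/deletion: replace
# ref at pos; insertion (ref == ""): insert alt before pos.
apply_edit <- function(seq, pos, ref, alt) {
  n <- nchar(seq)
  if (nzchar(ref)) {
    if (substr(seq, pos, pos + nchar(ref) - 1L) != ref)
      stopf("reference mismatch at position %d", pos)
    paste0(substr(seq, 1, pos - 1L), alt, substr(seq, pos + nchar(ref), n))
  } else {
    paste0(substr(seq, 1, pos - 1L), alt, substr(seq, pos, n))
  }
}
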