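#' Trim primers and assign reads to panel loci
#'
#' Each read is compared against every forward primer in the panel; it is
#' assigned to the unique locus whose primer matches the read prefix within
#' the mismatch budget, and the primer is removed. Reads matching no locus,
#' or more than one, are left unassigned with the reason recorded.
#'
#' @param reads Character vector of read sequences.
#' @param panel A `repeat_panel`.
#' @param max_primer_mismatches Allowed mismatches in the primer prefix.
#' @return Data frame with one row per read: `locus_id` (`NA` if
#'   unassigned), `insert` (read with primer removed), `reason` (`"ok"`,
#'   `"empty"`, `"no_match"`, or `"ambiguous"`).
#' @export
trim_and_assign <- function(reads, panel, max_primer_mismatches = 2L) {
  validate_panel(panel)
  if (max_primer_mismatches < 0) stopf("max_primer_mismatches must be >= 0")
  n <- length(reads)
  locus_ids <- names(panel)
  out <- data.frame(locus_id = rep(NA_character_, n),
                    insert = rep(NA_character_, n),
                    reason = rep("no_match", n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  empty <- is.na(reads) | !nzchar(reads)
  out$reason[empty] <- "empty"
  nhits <- integer(n)
  hit_locus <- rep(NA_integer_, n)
  for (j in seq_along(panel)) {
    primer <- panel[[j]]$fwd_primer
    pl <- nchar(primer)
    cand <- which(!empty & nchar(reads) >= pl)
    if (!length(cand)) next
    mm <- string_mismatches(substr(reads[cand], 1L, pl), primer)
    ok <- cand[mm <= max_primer_mismatches]
    nhits[ok] <- nhits[ok] + 1L
    hit_locus[ok] <- j
  }
  assigned <- nhits == 1L
  out$locus_id[assigned] <- locus_ids[hit_locus[assigned]]
  out$insert[assigned] <- substring(
    reads[assigned],
    nchar(vapply(panel, `[[`, "", "fwd_primer"))[hit_locus[assigned]] + 1L)
  out$reason[assigned] <- "ok"
  out$reason[nhits > 1L] <- "ambiguous"
  out
}

#' Extract the observed repeat length from primer-trimmed inserts
#'
#' Anchors the last `flank_anchor_len` bases of the left flank (leftmost
#' occurrence) and the first `flank_anchor_len` bases of the right flank
#' (first occurrence right of the left anchor) in each insert. The sequence
#' spanned between the anchors must be a pure repeat run of the locus unit
#' with a whole number of copies; otherwise the read is flagged unusable.
#' Anchoring failures never raise errors, only `usable = FALSE`.
#'
#' @param inserts Character vector of primer-trimmed read sequences.
#' @param locus A [repeat_locus()].
#' @param flank_anchor_len Anchor length in bp (>= 4).
#' @param max_flank_mismatches Mismatches tolerated in each anchor (the
#'   repeat-run check itself is always exact).
#' @return Data frame with columns `locus_id`, `observed_repeat_count`
#'   (`NA` when unusable), `usable`.
#' @export
extract_repeat_count <- function(inserts, locus, flank_anchor_len = 6L,
                                 max_flank_mismatches = 0L) {
  if (flank_anchor_len < 4) stopf("flank_anchor_len must be >= 4")
  nl <- nchar(locus$left_flank)
  if (flank_anchor_len > nl) stopf("anchor longer than flank")
  la <- substr(locus$left_flank, nl - flank_anchor_len + 1L, nl)
  ra <- substr(locus$right_flank, 1L, flank_anchor_len)
  ulen <- nchar(locus$repeat_unit)
  n <- length(inserts)
  observed <- rep(NA_integer_, n)
  usable <- logical(n)
  if (n > 0) {
    if (max_flank_mismatches == 0) {
      lpos <- regexpr(la, inserts, fixed = TRUE)
      tail_start <- ifelse(lpos > 0, lpos + flank_anchor_len, 1L)
      tails <- substring(inserts, tail_start)
      rrel <- regexpr(ra, tails, fixed = TRUE)
      found <- lpos > 0 & rrel > 0
      span <- integer(n)
      span[found] <- rrel[found] - 1L
      tract <- substr(tails, 1L, pmax(span, 0L))
      whole <- span %% ulen == 0
      count <- span %/% ulen
      pure <- found & whole &
        tract == strrep(locus$repeat_unit, pmax(count, 0L))
      usable <- found & whole & pure
      observed[usable] <- count[usable]
    } else {
      subj <- Biostrings::DNAStringSet(inserts)
      lm <- Biostrings::vmatchPattern(la, subj,
                                      max.mismatch = max_flank_mismatches)
      rm_ <- Biostrings::vmatchPattern(ra, subj,
                                       max.mismatch = max_flank_mismatches)
      for (i in seq_len(n)) {
        ls <- Biostrings::startIndex(lm)[[i]]
        rs <- Biostrings::startIndex(rm_)[[i]]
        if (is.null(ls) || !length(ls) || is.null(rs) || !length(rs)) next
        lstart <- min(ls)
        lend <- lstart + flank_anchor_len - 1L
        rs <- rs[rs > lend]
        if (!length(rs)) next
        rstart <- min(rs)
        span <- rstart - lend - 1L
        if (span < 0 || span %% ulen != 0) next
        tract <- substr(inserts[i], lend + 1L, rstart - 1L)
        if (tract != strrep(locus$repeat_unit, span %/% ulen)) next
        usable[i] <- TRUE
        observed[i] <- as.integer(span %/% ulen)
      }
    }
  }
  data.frame(locus_id = rep(locus$locus_id, n),
             observed_repeat_count = observed, usable = usable,
             stringsAsFactors = FALSE)
}

#' Count reads for one sample against a panel
#'
#' Convenience wrapper: [trim_and_assign()] then [extract_repeat_count()]
#' per locus.
#'
#' @param reads Character vector of read sequences.
#' @param panel A `repeat_panel`.
#' @param sample_id Sample label attached to the observations.
#' @param max_primer_mismatches,flank_anchor_len,max_flank_mismatches Passed
#'   through to the two steps.
#' @return Observation data frame (`sample_id`, `locus_id`,
#'   `observed_repeat_count`, `usable`), one row per assigned read.
#' @export
count_sample <- function(reads, panel, sample_id,
                         max_primer_mismatches = 2L, flank_anchor_len = 6L,
                         max_flank_mismatches = 0L) {
  asg <- trim_and_assign(reads, panel, max_primer_mismatches)
  keep <- !is.na(asg$locus_id)
  obs <- lapply(names(panel), function(lid) {
    ins <- asg$insert[keep & asg$locus_id == lid]
    if (!length(ins)) return(NULL)
    cbind(sample_id = sample_id,
          extract_repeat_count(ins, panel[[lid]], flank_anchor_len,
                               max_flank_mismatches))
  })
  out <- do.call(rbind, obs)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), locus_id = character(0),
                      observed_repeat_count = integer(0), usable = logical(0))
  out
}

#' Tabulate indel counts and VAFs
#'
#' Reduces usable repeat-length observations to one row per
#' `(sample, locus, offset)` with `offset != 0` measured in repeat units
#' relative to wild type. For each locus the offset set is the union over
#' *all* samples, zero-filled, so wild-type controls contribute explicit
#' 0-VAF rows for tumour-only offsets. `vaf` is
#' `mutant_reads / (mutant_reads + wt_reads)` (`NA` when that denominator is
#' 0). Samples with reads at a locus but no usable ones are dropped from
#' that locus with a warning.
#'
#' @param observations Observation data frame as from [count_sample()] or
#'   [simulate_cohort()].
#' @param panel A `repeat_panel` (source of wild-type repeat counts).
#' @return An indel count table: `sample_id`, `locus_id`, `offset`,
#'   `mutant_reads`, `wt_reads`, `total_usable`, `vaf`.
#' @export
tabulate_indels <- function(observations, panel) {
  validate_panel(panel)
  need <- c("sample_id", "locus_id", "observed_repeat_count", "usable")
  if (!all(need %in% names(observations)))
    stopf("observations must have columns %s", paste(need, collapse = ", "))
  wt <- setNames(vapply(panel, `[[`, 0L, "wt_repeat_count"), names(panel))
  res <- list()
  for (lid in intersect(names(panel), unique(observations$locus_id))) {
    sub_all <- observations[observations$locus_id == lid, , drop = FALSE]
    sub <- sub_all[sub_all$usable, , drop = FALSE]
    dropped <- setdiff(unique(sub_all$sample_id), unique(sub$sample_id))
    if (length(dropped))
      warning(sprintf("locus %s: no usable reads for sample(s) %s; excluded",
                      lid, paste(dropped, collapse = ", ")), call. = FALSE)
    if (!nrow(sub)) next
    offset <- sub$observed_repeat_count - wt[[lid]]
    offs <- sort(setdiff(unique(offset), 0L))
    samples <- unique(sub$sample_id)
    tab <- table(factor(sub$sample_id, levels = samples),
                 factor(offset, levels = sort(unique(c(0L, offset)))))
    total <- rowSums(tab)
    wt_reads <- if ("0" %in% colnames(tab)) tab[, "0"] else rep(0L, nrow(tab))
    for (off in offs) {
      mut <- tab[, as.character(off)]
      denom <- mut + wt_reads
      res[[length(res) + 1L]] <- data.frame(
        sample_id = samples, locus_id = lid, offset = off,
        mutant_reads = as.integer(mut), wt_reads = as.integer(wt_reads),
        total_usable = as.integer(total),
        vaf = ifelse(denom > 0, mut / denom, NA_real_),
        row.names = NULL)
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(0), locus_id = character(0),
                      offset = integer(0), mutant_reads = integer(0),
                      wt_reads = integer(0), total_usable = integer(0),
                      vaf = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$locus_id, out$offset, out$sample_id), , drop = FALSE]
}
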