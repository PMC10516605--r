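#' Rank the most common distinct reads of a sample
#'
#' Distinct read sequences ranked by copy number (ties broken
#' lexicographically). Frequencies are computed over *all* reads of the
#' sample, not just the reported top `K`, so a variant's reported frequency
#' does not depend on `K`.
#'
#' @param reads Character vector of read sequences (one element per read).
#' @param K Number of top sequences to keep (>= 1; 300 by default, the upper
#'   end of the customary 100-300 window).
#' @return Data frame `sequence`, `count`, `frequency`, `rank`.
#' @export
top_common_reads <- function(reads, K = 300L) {
  if (K < 1) stopf("K must be >= 1")
  if (!length(reads)) {
    return(data.frame(sequence = character(0), count = integer(0),
                      frequency = numeric(0), rank = integer(0)))
  }
  tab <- table(reads)
  ord <- order(-as.integer(tab), names(tab))
  counts <- as.integer(tab)[ord]
  out <- data.frame(sequence = names(tab)[ord], count = counts,
                    frequency = counts / length(reads),
                    rank = seq_along(counts), row.names = NULL)
  head(out, K)
}

#' Globally align a read to its reference amplicon and extract the edits
#'
#' Needleman-Wunsch global alignment with unit mismatch and gap costs
#' (via [Biostrings::pairwiseAlignment()]), followed by normalisation of
#' every indel to its leftmost equivalent placement — an indel inside a
#' homopolymer or repeat is always reported at the run's first position, so
#' identical mutations from different reads aggregate under one key.
#'
#' Edit conventions: substitutions carry the 1-based reference position and
#' single-base `ref`/`alt`; deletions carry the first deleted reference
#' position, the deleted bases as `ref`, and `alt = ""`; insertions carry
#' the reference position *before which* the bases are inserted,
#' `ref = ""`, and the inserted bases as `alt`.
#'
#' @param read_sequence,reference Non-empty DNA strings.
#' @return Data frame `type` (`"sub"`, `"del"`, `"ins"`), `position`,
#'   `ref_allele`, `alt_allele`; zero rows when the sequences are identical.
#' @export
align_to_reference <- function(read_sequence, reference) {
  if (!nzchar(read_sequence) || !nzchar(reference))
    stopf("sequences must be non-empty")
  empty <- data.frame(type = character(0), position = integer(0),
                      ref_allele = character(0), alt_allele = character(0))
  if (read_sequence == reference) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(read_sequence, reference,
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refc <- strsplit(reference, "")[[1]]
  ops <- list()
  flush <- function(type, pos, ref, alt)
    ops[[length(ops) + 1L]] <<- list(type = type, pos = pos, ref = ref,
                                     alt = alt)
  refpos <- 0L
  run_type <- ""
  run_start <- 0L
  run_seq <- character(0)
  end_run <- function() {
    if (run_type == "ins") {
      flush("ins", run_start, "", paste(run_seq, collapse = ""))
    } else if (run_type == "del") {
      flush("del", run_start, paste(run_seq, collapse = ""), "")
    }
    run_type <<- ""
    run_seq <<- character(0)
  }
  for (i in seq_along(p)) {
    if (s[i] == "-") {                       # read has an extra base
      if (run_type != "ins") {
        end_run()
        run_type <- "ins"
        run_start <- refpos + 1L
      }
      run_seq <- c(run_seq, p[i])
    } else if (p[i] == "-") {                # read lacks a reference base
      refpos <- refpos + 1L
      if (run_type != "del") {
        end_run()
        run_type <- "del"
        run_start <- refpos
      }
      run_seq <- c(run_seq, s[i])
    } else {
      end_run()
      refpos <- refpos + 1L
      if (p[i] != s[i]) flush("sub", refpos, s[i], p[i])
    }
  }
  end_run()
  # left-normalise indels
  for (j in seq_along(ops)) {
    op <- ops[[j]]
    if (op$type == "del") {
      l <- nchar(op$ref)
      pos <- op$pos
      while (pos > 1L && refc[pos - 1L] == refc[pos + l - 1L]) pos <- pos - 1L
      op$pos <- pos
      op$ref <- paste(refc[pos:(pos + l - 1L)], collapse = "")
    } else if (op$type == "ins") {
      l <- nchar(op$alt)
      pos <- op$pos
      alt <- op$alt
      while (pos > 1L && substr(alt, l, l) == refc[pos - 1L]) {
        alt <- paste0(refc[pos - 1L], substr(alt, 1L, l - 1L))
        pos <- pos - 1L
      }
      op$pos <- pos
      op$alt <- alt
    }
    ops[[j]] <- op
  }
  out <- data.frame(
    type = vapply(ops, `[[`, "", "type"),
    position = vapply(ops, function(o) as.integer(o$pos), 0L),
    ref_allele = vapply(ops, `[[`, "", "ref"),
    alt_allele = vapply(ops, `[[`, "", "alt"),
    row.names = NULL)
  out[order(out$position, out$type), , drop = FALSE]
}

#' Call mutations from ranked reads
#'
#' Aligns each top-ranked distinct read to the reference, pools identical
#' edits across reads (frequencies add), and reports every edit carried by
#' strictly more than `min_frequency` of the sample's reads. Discovery is
#' restricted to the top-`K` list handed in; frequencies are the all-read
#' frequencies computed by [top_common_reads()].
#'
#' @param ranked_reads Output of [top_common_reads()].
#' @param reference Reference amplicon sequence.
#' @param min_frequency Strict reporting threshold (default 0.04, i.e.
#'   "greater than 4%").
#' @param locus_id Label attached to the calls.
#' @return Data frame `locus_id`, `type`, `position`, `ref_allele`,
#'   `alt_allele`, `frequency`, `n_supporting_reads`, `supporting_ranks`
#'   (list column), sorted by frequency (descending).
#' @export
call_mutations <- function(ranked_reads, reference, min_frequency = 0.04,
                           locus_id = NA_character_) {
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ranked_reads))) {
    seqi <- ranked_reads$sequence[i]
    if (seqi == reference) next
    ops <- align_to_reference(seqi, reference)
    for (j in seq_len(nrow(ops))) {
      key <- sprintf("%s:%d:%s>%s", ops$type[j], ops$position[j],
                     ops$ref_allele[j], ops$alt_allele[j])
      cur <- acc[[key]] %||% list(op = ops[j, ], freq = 0, ranks = integer(0))
      cur$freq <- cur$freq + ranked_reads$frequency[i]
      cur$ranks <- c(cur$ranks, ranked_reads$rank[i])
      acc[[key]] <- cur
    }
  }
  keys <- ls(acc)
  if (!length(keys)) {
    return(data.frame(locus_id = character(0), type = character(0),
                      position = integer(0), ref_allele = character(0),
                      alt_allele = character(0), frequency = numeric(0),
                      n_supporting_reads = integer(0)))
  }
  rows <- lapply(keys, function(k) {
    e <- acc[[k]]
    cbind(locus_id = locus_id, e$op,
          data.frame(frequency = e$freq, n_supporting_reads = length(e$ranks)))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "pos"] <- "position"
  out$supporting_ranks <- I(lapply(keys, function(k) sort(acc[[k]]$ranks)))
  out <- out[out$frequency > min_frequency, , drop = FALSE]
  out <- out[order(-out$frequency, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call hotspot pipeline for a sample
#'
#' @param reads Character vector of all reads assigned to the amplicon.
#' @param reference Reference amplicon sequence.
#' @param K Top distinct reads to inspect.
#' @param min_frequency Strict reporting threshold.
#' @param locus_id Label for the calls.
#' @return See [call_mutations()].
#' @export
hotspot_call <- function(reads, reference, K = 300L, min_frequency = 0.04,
                         locus_id = NA_character_) {
  call_mutations(top_common_reads(reads, K), reference, min_frequency,
                 locus_id)
}
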