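#' Construct a mononucleotide-repeat amplicon locus
#'
#' A `repeat_locus` describes one amplicon target: primers, flanking
#' sequences, the repeat unit and its wild-type copy number. The repeat run
#' must be maximal — the left flank may not end with, and the right flank may
#' not start with, the adjacent repeat base — so that the observed run length
#' of a read is unambiguous.
#'
#' @param locus_id Short unique identifier.
#' @param left_flank,right_flank Flanking DNA (>= 15 nt each).
#' @param repeat_unit Repeat unit (length-1 string for mononucleotide
#'   repeats).
#' @param wt_repeat_count Wild-type repeat copy number (>= 5).
#' @param fwd_primer,rev_primer Primer sequences bounding the amplicon.
#' @param is_msi_marker Logical; `TRUE` for fragment-analysis MSI markers,
#'   `FALSE` for coding frameshift targets.
#' @return An object of class `repeat_locus`. `product_size_wt` is the length
#'   in bp of the full wild-type amplicon.
#' @export
#' @examples
#' loc <- repeat_locus("demo-A24", strrep("CGT", 5), "A", 24,
#'                     strrep("TGC", 5), strrep("ACGT", 5), strrep("GTCA", 5))
#' loc$product_size_wt
repeat_locus <- function(locus_id, left_flank, repeat_unit, wt_repeat_count,
                         right_flank, fwd_primer, rev_primer,
                         is_msi_marker = FALSE) {
  if (!is.character(locus_id) || length(locus_id) != 1 || !nzchar(locus_id))
    stopf("locus_id must be a non-empty string")
  if (!is_dna(repeat_unit) || nchar(repeat_unit) < 1)
    stopf("locus %s: repeat_unit must be a non-empty DNA string", locus_id)
  wt_repeat_count <- as.integer(wt_repeat_count)
  if (is.na(wt_repeat_count) || wt_repeat_count < 5)
    stopf("locus %s: wt_repeat_count must be an integer >= 5", locus_id)
  for (nm in c("left_flank", "right_flank", "fwd_primer", "rev_primer")) {
    v <- get(nm)
    if (!is_dna(v)) stopf("locus %s: %s must be a DNA string", locus_id, nm)
  }
  if (nchar(left_flank) < 15 || nchar(right_flank) < 15)
    stopf("locus %s: flanks must be >= 15 nt", locus_id)
  first_unit_base <- substr(repeat_unit, 1, 1)
  last_unit_base <- substr(repeat_unit, nchar(repeat_unit), nchar(repeat_unit))
  if (substr(left_flank, nchar(left_flank), nchar(left_flank)) == first_unit_base)
    stopf("locus %s: left_flank ends with the repeat base; repeat run would not be maximal",
          locus_id)
  if (substr(right_flank, 1, 1) == last_unit_base)
    stopf("locus %s: right_flank starts with the repeat base; repeat run would not be maximal",
          locus_id)
  structure(list(
    locus_id = locus_id,
    left_flank = left_flank,
    repeat_unit = repeat_unit,
    wt_repeat_count = wt_repeat_count,
    right_flank = right_flank,
    fwd_primer = fwd_primer,
    rev_primer = rev_primer,
    is_msi_marker = isTRUE(is_msi_marker),
    product_size_wt = nchar(fwd_primer) + nchar(left_flank) +
      nchar(repeat_unit) * wt_repeat_count + nchar(right_flank) +
      nchar(rev_primer)
  ), class = "repeat_locus")
}

#' @export
print.repeat_locus <- function(x, ...) {
  cat(sprintf("<repeat_locus %s: %s x %d, amplicon %d bp%s>\n",
              x$locus_id, x$repeat_unit, x$wt_repeat_count,
              x$product_size_wt,
              if (x$is_msi_marker) ", MSI marker" else ""))
  invisible(x)
}

#' Amplicon sequence of a locus
#'
#' @param locus A [repeat_locus()].
#' @param repeat_count Repeat copies to spell (default wild type).
#' @return The amplicon DNA string
#'   `fwd_primer + left_flank + unit^count + right_flank + rev_primer`.
#' @export
amplicon_seq <- function(locus, repeat_count = NULL) {
  n <- repeat_count %||% locus$wt_repeat_count
  if (n < 0) stopf("repeat_count must be >= 0")
  paste0(locus$fwd_primer, locus$left_flank,
         strrep(locus$repeat_unit, n),
         locus$right_flank, locus$rev_primer)
}

# The left anchor (last `anchor_len` bases of the left flank) must occur in
# the left flank only as its suffix, otherwise leftmost anchor search in a
# read could lock onto the wrong position.
anchor_ok <- function(left_flank, anchor_len) {
  anchor <- substr(left_flank, nchar(left_flank) - anchor_len + 1,
                   nchar(left_flank))
  hits <- gregexpr(anchor, left_flank, fixed = TRUE)[[1]]
  length(hits) == 1 && hits[1] == nchar(left_flank) - anchor_len + 1
}

#' Build an amplicon panel
#'
#' Missing flanks and primers are generated at random under `seed` (so a
#' given configuration always yields the same panel), subject to the
#' maximality and anchor-uniqueness constraints that make repeat-length
#' extraction deterministic.
#'
#' @param config A data frame with columns `locus_id`, `repeat_unit`,
#'   `wt_repeat_count`, and optionally `left_flank`, `right_flank`,
#'   `fwd_primer`, `rev_primer`, `is_msi_marker`.
#' @param seed Integer seed for generated sequence.
#' @param flank_len,primer_len Lengths for generated flanks and primers.
#' @param anchor_len Anchor length the extraction step will use; generated
#'   left flanks are constrained so the anchor is unique.
#' @return A `repeat_panel`: a named list of [repeat_locus()] objects.
#' @export
#' @examples
#' panel <- make_locus_panel(data.frame(
#'   locus_id = "mU12235-A24", repeat_unit = "A", wt_repeat_count = 24L))
#' panel[["mU12235-A24"]]
make_locus_panel <- function(config, seed = 1L, flank_len = 15L,
                             primer_len = 20L, anchor_len = 6L) {
  stopifnot(is.data.frame(config), nrow(config) >= 1)
  need <- c("locus_id", "repeat_unit", "wt_repeat_count")
  if (!all(need %in% names(config)))
    stopf("config must have columns %s", paste(need, collapse = ", "))
  get_col <- function(nm, i) {
    if (nm %in% names(config) && !is.na(config[[nm]][i]) &&
        nzchar(as.character(config[[nm]][i]))) as.character(config[[nm]][i])
    else NULL
  }
  loci <- with_seed(seed, {
    lapply(seq_len(nrow(config)), function(i) {
      unit <- as.character(config$repeat_unit[i])
      if (!is_dna(unit)) stopf("row %d: invalid repeat_unit", i)
      first_base <- substr(unit, 1, 1)
      last_base <- substr(unit, nchar(unit), nchar(unit))
      left <- get_col("left_flank", i)
      if (is.null(left)) {
        repeat {
          left <- random_dna(flank_len)
          if (substr(left, flank_len, flank_len) != first_base &&
              anchor_ok(left, anchor_len)) break
        }
      }
      right <- get_col("right_flank", i)
      if (is.null(right)) {
        repeat {
          right <- random_dna(flank_len)
          if (substr(right, 1, 1) != last_base) break
        }
      }
      fwd <- get_col("fwd_primer", i) %||% random_dna(primer_len)
      rev <- get_col("rev_primer", i) %||% random_dna(primer_len)
      msi <- if ("is_msi_marker" %in% names(config))
        isTRUE(config$is_msi_marker[i]) else FALSE
      repeat_locus(as.character(config$locus_id[i]), left, unit,
                   config$wt_repeat_count[i], right, fwd, rev,
                   is_msi_marker = msi)
    })
  })
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  panel <- structure(loci, class = "repeat_panel")
  validate_panel(panel)
  panel
}

#' Validate an amplicon panel
#'
#' Checks locus identifier uniqueness and that no two loci share a forward
#' primer (duplicate primers would make read assignment ambiguous for every
#' read).
#'
#' @param panel A `repeat_panel`.
#' @return The panel, invisibly; errors on violation.
#' @export
validate_panel <- function(panel) {
  if (!inherits(panel, "repeat_panel") || length(panel) == 0)
    stopf("not a repeat_panel")
  ids <- vapply(panel, `[[`, "", "locus_id")
  if (anyDuplicated(ids)) stopf("duplicate locus ids in panel")
  primers <- vapply(panel, `[[`, "", "fwd_primer")
  if (anyDuplicated(primers)) stopf("duplicate forward primers in panel")
  invisible(panel)
}

#' @export
print.repeat_panel <- function(x, ...) {
  cat(sprintf("<repeat_panel: %d loci (%d MSI markers)>\n", length(x),
              sum(vapply(x, `[[`, FALSE, "is_msi_marker"))))
  for (loc in x) print(loc)
  invisible(x)
}

#' Configuration of the bundled demonstration panel
#'
#' Seven fragment-analysis MSI markers (mononucleotide tracts from A24 to
#' A67) plus five coding mononucleotide-repeat frameshift targets named after
#' recurrently mutated genes in MMR-deficient mouse intestinal tumours. The
#' flanks, primers, and coding-locus repeat lengths are synthetic stand-ins
#' generated under a fixed seed; only the marker names and tract lengths of
#' the MSI markers follow the published panel.
#'
#' @return A data frame accepted by [make_locus_panel()].
#' @export
demo_panel_config <- function() {
  data.frame(
    locus_id = c("mU12235-A24", "mL24372-A27", "mBat30", "mBat37",
                 "mBat59", "mBat64", "mBat67",
                 "Asxl1", "Maz", "Xirp1", "Senp6", "Nacad"),
    repeat_unit = c(rep("A", 7), "G", "G", "A", "A", "T"),
    wt_repeat_count = c(24L, 27L, 30L, 37L, 59L, 64L, 67L,
                        8L, 6L, 9L, 10L, 7L),
    is_msi_marker = c(rep(TRUE, 7), rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
}

#' The bundled demonstration panel
#'
#' @param seed Seed used to generate flanks and primers.
#' @return A `repeat_panel` of 12 loci; see [demo_panel_config()].
#' @export
demo_panel <- function(seed = 20260115L) {
  make_locus_panel(demo_panel_config(), seed = seed)
}

#' Write / read a panel
#'
#' The panel is stored as a FASTA of wild-type amplicon sequences plus a JSON
#' sidecar holding the structured fields; the JSON is authoritative on read
#' and the FASTA is checked against it.
#'
#' @param panel A `repeat_panel`.
#' @param fasta_path,meta_path Output paths.
#' @return `write_panel` returns the paths invisibly; `read_panel` returns
#'   the reconstructed `repeat_panel`.
#' @export
write_panel <- function(panel, fasta_path, meta_path) {
  validate_panel(panel)
  seqs <- Biostrings::DNAStringSet(vapply(panel, amplicon_seq, ""))
  names(seqs) <- names(panel)
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- lapply(panel, function(l) l[setdiff(names(l), "product_size_wt")])
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fasta = fasta_path, meta = meta_path))
}

#' @rdname write_panel
#' @export
read_panel <- function(fasta_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  loci <- lapply(meta, function(m) {
    repeat_locus(m$locus_id, m$left_flank, m$repeat_unit, m$wt_repeat_count,
                 m$right_flank, m$fwd_primer, m$rev_primer,
                 is_msi_marker = isTRUE(m$is_msi_marker))
  })
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  panel <- structure(loci, class = "repeat_panel")
  validate_panel(panel)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  stored <- as.character(seqs)
  built <- vapply(panel, amplicon_seq, "")
  if (!identical(unname(stored[names(panel)]), unname(built)))
    stopf("panel FASTA does not match its JSON metadata")
  panel
}
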