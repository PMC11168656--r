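#' Amplicon reference for indel quantification
#'
#' @param sequence Reference amplicon sequence.
#' @param cut_site 0-based cut boundary (the nuclease cut lies between
#'   positions `cut_site` and `cut_site + 1` in 1-based coordinates).
#' @param window_halfwidth Half-width w of the quantification window: an
#'   indel counts as an edit iff it intersects positions
#'   `cut_site - w .. cut_site + w` (0-based).
#' @param snp Optional `list(offset = <0-based>, ref = <base>,
#'   alt = <base>)` describing a SNV used for allele assignment.
#' @return An object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(sequence, cut_site,
                               window_halfwidth = 10L, snp = NULL) {
  if (!is_dna(sequence)) stopf("sequence must be a plain ACGT string")
  len <- nchar(sequence)
  if (cut_site < 0 || cut_site >= len) stopf("cut_site outside sequence")
  if (!is.null(snp)) {
    stopifnot(all(c("offset", "ref", "alt") %in% names(snp)))
    if (snp$offset < 0 || snp$offset >= len)
      stopf("snp offset outside sequence")
    if (substr(sequence, snp$offset + 1L, snp$offset + 1L) != snp$ref)
      stopf("reference base at snp offset is not snp$ref")
    if (snp$ref == snp$alt) stopf("snp ref and alt must differ")
  }
  structure(list(sequence = sequence, cut_site = as.integer(cut_site),
                 window_halfwidth = as.integer(window_halfwidth),
                 snp = snp),
            class = "amplicon_reference")
}

# Does any op in `ops` intersect the 1-based window [lo, hi]?
# Returns the subset that does.
ops_in_window <- function(ops, lo, hi) {
  if (nrow(ops) == 0L) return(ops)
  keep <- ifelse(ops$op == "D",
                 ops$ref_start <= hi & (ops$ref_start + ops$len - 1L) >= lo,
                 ops$ref_start >= lo - 1L & ops$ref_start <= hi)
  ops[keep, , drop = FALSE]
}

#' Call indels around the cut site
#'
#' Classifies each aligned read by the indels that intersect the
#' quantification window around the cut site: `deletion`, `insertion`,
#' `complex` (both op types), or `unedited` (no window-overlapping indel;
#' substitutions never count as edits). Indels wholly outside the window
#' are ignored. Reads whose alignment identity falls below the threshold
#' are `unalignable` and carry no call. The net length change `delta` sums
#' insertion minus deletion lengths over window-overlapping indels.
#'
#' @param alignments An `amplicon_alignments` object from [align_reads()].
#' @param reference An [amplicon_reference()] (supplies cut site, window
#'   and optional SNV).
#' @return Data.frame (one row per read): `read_id`, `class`, `delta`,
#'   `allele` ("ref"/"alt"/"unassigned", or NA when the reference carries
#'   no SNV).
#' @export
call_indels <- function(alignments, reference) {
  stopifnot(inherits(alignments, "amplicon_alignments"),
            inherits(reference, "amplicon_reference"))
  w <- reference$window_halfwidth
  lo <- reference$cut_site - w + 1L   # 1-based window bounds
  hi <- reference$cut_site + w + 1L
  n <- alignments$n
  cls <- character(n)
  delta <- integer(n)
  minid <- alignments$params$min_identity
  for (i in seq_len(n)) {
    if (alignments$identity[i] < minid) {
      cls[i] <- "unalignable"; delta[i] <- NA_integer_; next
    }
    ops <- ops_in_window(alignments$ops[[i]], lo, hi)
    if (nrow(ops) == 0L) {
      cls[i] <- "unedited"; delta[i] <- 0L; next
    }
    has_d <- any(ops$op == "D"); has_i <- any(ops$op == "I")
    cls[i] <- if (has_d && has_i) "complex"
              else if (has_d) "deletion" else "insertion"
    delta[i] <- sum(ops$len[ops$op == "I"]) - sum(ops$len[ops$op == "D"])
  }
  allele <- if (is.null(reference$snp)) rep(NA_character_, n)
            else assign_allele(alignments, reference$snp)
  allele[cls == "unalignable"] <- NA_character_
  data.frame(read_id = alignments$read_ids, class = cls, delta = delta,
             allele = allele, stringsAsFactors = FALSE)
}

#' @rdname call_indels
#' @param alignment An `amplicon_alignments` with a single read.
#' @export
call_indel <- function(alignment, reference) call_indels(alignment, reference)

#' Assign each read to an allele at a SNV
#'
#' The read base aligned to the SNV reference position decides the allele:
#' the alt base gives "alt", the ref base "ref"; a deletion spanning the
#' SNV, or any other base (including N), gives "unassigned".
#'
#' @param alignments An `amplicon_alignments` object.
#' @param snp `list(offset = <0-based>, ref = , alt = )`.
#' @return Character vector of "ref"/"alt"/"unassigned" per read.
#' @export
assign_allele <- function(alignments, snp) {
  stopifnot(inherits(alignments, "amplicon_alignments"))
  pos1 <- snp$offset + 1L
  n <- alignments$n
  out <- rep("ref", n)   # no mismatch and no deletion at the SNV => ref
  mm <- alignments$mismatches
  at_snp <- mm[mm$SubjectStart == pos1, , drop = FALSE]
  if (nrow(at_snp)) {
    base <- as.character(at_snp$PatternSubstring)
    out[at_snp$PatternId] <- ifelse(base == snp$alt, "alt", "unassigned")
  }
  for (i in seq_len(n)) {
    ops <- alignments$ops[[i]]
    del <- ops[ops$op == "D", , drop = FALSE]
    if (nrow(del) &&
        any(del$ref_start <= pos1 & del$ref_start + del$len - 1L >= pos1))
      out[i] <- "unassigned"
  }
  out
}

#' Summarise editing over a set of indel calls
#'
#' Overall editing rate is 100 * edited / aligned; unalignable reads are
#' excluded from the denominator. When calls carry allele labels,
#' per-allele rates are computed over assigned reads only.
#'
#' @param records Data.frame from [call_indels()].
#' @param reference The [amplicon_reference()] the calls were made against.
#' @return An `editing_summary`: list with `n_total` (aligned reads),
#'   `n_edited`, `indel_pct`, and a `per_allele` data.frame when the
#'   reference has a SNV.
#' @export
summarize_editing <- function(records, reference) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  aligned <- records[records$class != "unalignable", , drop = FALSE]
  if (nrow(aligned) == 0L) stopf("no aligned reads to summarise")
  edited_classes <- c("deletion", "insertion", "complex")
  n_total <- nrow(aligned)
  n_edited <- sum(aligned$class %in% edited_classes)
  out <- list(n_total = n_total, n_edited = n_edited,
              indel_pct = 100 * n_edited / n_total,
              n_unalignable = nrow(records) - n_total)
  if (!is.null(reference$snp)) {
    per <- lapply(c("ref", "alt"), function(a) {
      sub <- aligned[!is.na(aligned$allele) & aligned$allele == a, ,
                     drop = FALSE]
      data.frame(allele = a, n = nrow(sub),
                 n_edited = sum(sub$class %in% edited_classes),
                 indel_pct = if (nrow(sub)) 100 *
                   sum(sub$class %in% edited_classes) / nrow(sub)
                 else NA_real_)
    })
    out$per_allele <- do.call(rbind, per)
    out$n_unassigned <- sum(!is.na(aligned$allele) &
                              aligned$allele == "unassigned")
  }
  class(out) <- "editing_summary"
  out
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("Editing summary: %d/%d reads edited (%.2f%%)\n",
              x$n_edited, x$n_total, x$indel_pct))
  if (!is.null(x$per_allele)) {
    for (i in seq_len(nrow(x$per_allele)))
      cat(sprintf("  %s allele: %d/%d (%.2f%%)\n",
                  x$per_allele$allele[i], x$per_allele$n_edited[i],
                  x$per_allele$n[i], x$per_allele$indel_pct[i]))
  }
  invisible(x)
}

#' Quantify editing of amplicon reads in one call
#'
#' Convenience wrapper: align, call indels, summarise.
#'
#' @inheritParams align_reads
#' @param reference An [amplicon_reference()].
#' @return List with `records` (per-read calls) and `summary`
#'   (`editing_summary`).
#' @export
quantify_amplicon <- function(reads, reference, params = list(),
                              orient = TRUE, read_ids = NULL) {
  aln <- align_reads(reads, reference, params = params, orient = orient,
                     read_ids = read_ids)
  records <- call_indels(aln, reference)
  list(records = records, summary = summarize_editing(records, reference))
}

#' Normalise off-target by on-target efficiency
#'
#' @param on_efficiency On-target editing percentage (> 0).
#' @param off_efficiencies Off-target editing percentages.
#' @return Data.frame (off_efficiency, ratio, exceeds_on): ratio_i =
#'   off_i / on; ratios above 1 are flagged, never clipped.
#' @export
normalize_specificity <- function(on_efficiency, off_efficiencies) {
  if (!is.numeric(on_efficiency) || length(on_efficiency) != 1L ||
      is.na(on_efficiency) || on_efficiency <= 0)
    stopf("on_efficiency must be a single positive number")
  if (any(off_efficiencies < 0)) stopf("efficiencies must be >= 0")
  ratio <- off_efficiencies / on_efficiency
  data.frame(off_efficiency = off_efficiencies, ratio = ratio,
             exceeds_on = ratio > 1)
}
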