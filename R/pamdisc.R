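#' Extract the randomized PAM 5-mer from a reporter read
#'
#' Locates the first exact occurrence of the upstream anchor (the 15-nt
#' suffix of the upstream homology arm, ending in the GFP ATG) and reads
#' the 5 bases that follow; the next 3 bases must equal the downstream
#' anchor (the start of the printed protospacer). Reads lacking this layout
#' or containing non-ACGT bases in the 5-mer are rejected with a tagged
#' status, not an error.
#'
#' @param reads Character vector of reads.
#' @param upstream_anchor,downstream_anchor Literal anchor sequences.
#' @param max_mismatch Allowed mismatches in the upstream anchor (0 =
#'   exact matching; 1 tolerates a single sequencing error).
#' @return Data.frame (read index order preserved): `pam` (5-mer or NA) and
#'   `status` in `ok`, `no_upstream_anchor`, `downstream_mismatch`,
#'   `non_acgt_base`, `truncated`.
#' @export
extract_random_region <- function(reads,
                                  upstream_anchor = "TTGTTTGCCACCATG",
                                  downstream_anchor = "GGA",
                                  max_mismatch = 0L) {
  if (!nzchar(upstream_anchor) || !nzchar(downstream_anchor))
    stopf("anchors must be non-empty")
  n <- length(reads)
  ua_len <- nchar(upstream_anchor)
  da_len <- nchar(downstream_anchor)
  if (max_mismatch == 0L) {
    hit <- regexpr(upstream_anchor, reads, fixed = TRUE)
    anchor_end <- ifelse(hit > 0L, hit + ua_len - 1L, NA_integer_)
  } else {
    m <- Biostrings::vmatchPattern(upstream_anchor, DNAStringSet(reads),
                                   max.mismatch = max_mismatch)
    anchor_end <- vapply(m, function(r)
      if (length(r)) IRanges::end(r)[1L] else NA_integer_, integer(1))
  }
  pam <- substr(reads, anchor_end + 1L, anchor_end + 5L)
  down <- substr(reads, anchor_end + 6L, anchor_end + 5L + da_len)
  status <- rep("ok", n)
  status[is.na(anchor_end)] <- "no_upstream_anchor"
  have <- status == "ok"
  short <- have & nchar(reads) < anchor_end + 5L + da_len
  status[short] <- "truncated"
  have <- status == "ok"
  status[have & down != downstream_anchor] <- "downstream_mismatch"
  have <- status == "ok"
  status[have & !grepl("^[ACGT]{5}$", pam)] <- "non_acgt_base"
  pam[status != "ok"] <- NA_character_
  data.frame(pam = pam, status = status, stringsAsFactors = FALSE)
}

#' Classify reporter reads by reading-frame outcome
#'
#' Globally aligns each read to the rendered reporter amplicon and sums the
#' lengths of indels intersecting the 29-nt insert (random region +
#' protospacer) into a net length change `delta`. Classes:
#' `unedited` (no indel in the insert; substitution-only reads included),
#' `in_frame_edit` (delta != 0 and (29 + delta) mod 3 = 0, i.e. GFP
#' restored), `out_of_frame_edit` (any other indel outcome), and
#' `unalignable` (identity below threshold).
#'
#' @param reads Character vector of reads.
#' @param reference A `reporter_construct` with a concrete random region,
#'   or the rendered amplicon as a string (then `insert_window` gives the
#'   1-based insert bounds).
#' @param params Alignment parameters, see [align_reads()].
#' @param insert_window Optional 1-based `c(lo, hi)` of the insert within
#'   the reference; derived automatically from a `reporter_construct`.
#' @param insert_len Unedited insert length (default 29 nt).
#' @return Data.frame with `class` and `delta` per read.
#' @export
classify_frame <- function(reads, reference, params = list(),
                           insert_window = NULL, insert_len = 29L) {
  if (inherits(reference, "reporter_construct")) {
    if (grepl("N", reference$random_region))
      stopf("reference random_region must be concrete (got '%s')",
            reference$random_region)
    lo <- insert_start(reference) + 1L
    insert_window <- c(lo, lo + reference$insert_len - 1L)
    insert_len <- reference$insert_len
    reference <- render_amplicon(reference)
  }
  if (is.null(insert_window))
    stopf("insert_window is required when reference is a plain string")
  aln <- align_reads(reads, reference, params = params, orient = FALSE)
  classify_frame_aln(aln, insert_window, insert_len)
}

# Frame classification from precomputed alignments.
classify_frame_aln <- function(aln, insert_window, insert_len = 29L) {
  n <- aln$n
  minid <- aln$params$min_identity
  cls <- character(n)
  delta <- integer(n)
  for (i in seq_len(n)) {
    if (aln$identity[i] < minid) {
      cls[i] <- "unalignable"; delta[i] <- NA_integer_; next
    }
    ops <- ops_in_window(aln$ops[[i]], insert_window[1L], insert_window[2L])
    if (nrow(ops) == 0L) {
      cls[i] <- "unedited"; delta[i] <- 0L; next
    }
    d <- sum(ops$len[ops$op == "I"]) - sum(ops$len[ops$op == "D"])
    delta[i] <- d
    cls[i] <- if (d != 0L && (insert_len + d) %% 3L == 0L) "in_frame_edit"
              else "out_of_frame_edit"
  }
  data.frame(class = cls, delta = delta, stringsAsFactors = FALSE)
}

#' Count PAM 5-mers from a GFP-selected read pool
#'
#' The discovery pipeline of the PAM screen: (a) anchor each read and
#' extract the 5-nt random region, (b) align to the reporter rendered with
#' that 5-mer and keep reads classified `in_frame_edit` (only in-frame
#' mutated targets are informative about cleavage), then (c) count the
#' surviving 5-mers. Filter provenance is recorded so every removed read is
#' accounted for.
#'
#' @param reads Character vector of reads from the GFP-positive pool.
#' @param design `reporter_construct` template.
#' @param params Alignment parameters for frame classification.
#' @param max_mismatch Anchor mismatches tolerated, see
#'   [extract_random_region()].
#' @param sample_id Free-text metadata label.
#' @return A `pam_count_table`: named integer vector `counts` (5-mer ->
#'   count), `n_total`, `empty` flag and `provenance` counts.
#' @export
build_pam_counts <- function(reads, design = reporter_construct(),
                             params = list(), max_mismatch = 0L,
                             sample_id = NA_character_) {
  stopifnot(inherits(design, "reporter_construct"))
  ex <- extract_random_region(reads, design$upstream_anchor,
                              substr(design$protospacer, 1L, 3L),
                              max_mismatch = max_mismatch)
  prov <- c(n_input = length(reads),
            n_anchor_rejected = sum(ex$status != "ok"))
  keep <- which(ex$status == "ok")
  counts <- integer(0)
  n_frame <- c(unalignable = 0L, unedited = 0L, out_of_frame_edit = 0L,
               in_frame_edit = 0L)
  if (length(keep)) {
    # group reads by extracted 5-mer so each group aligns against the
    # reporter rendered with its own PAM
    groups <- split(keep, ex$pam[keep])
    kept_pams <- character(0)
    for (pam in names(groups)) {
      idx <- groups[[pam]]
      ref <- reporter_construct(design$upstream_homology, pam,
                                design$protospacer,
                                design$downstream_homology)
      cf <- classify_frame(reads[idx], ref, params = params)
      tab <- table(factor(cf$class, levels = names(n_frame)))
      n_frame <- n_frame + as.integer(tab)
      n_if <- sum(cf$class == "in_frame_edit")
      if (n_if > 0L) counts[pam] <- n_if
    }
  }
  if (length(counts)) counts <- counts[order(names(counts))]
  structure(list(
    counts = counts, n_total = sum(counts),
    empty = length(counts) == 0L,
    provenance = c(as.list(prov), as.list(n_frame)),
    metadata = list(sample_id = sample_id, weighting = "per-read")
  ), class = "pam_count_table")
}

#' Build a pam_count_table directly from 5-mer counts
#'
#' For pre-filtered data (or unit tests): wraps a named count vector in the
#' container [compute_profile()] and [compute_wheel()] consume.
#'
#' @param counts Named integer vector, names are ACGT 5-mers.
#' @param sample_id Metadata label.
#' @return A `pam_count_table`.
#' @export
pam_count_table <- function(counts, sample_id = NA_character_) {
  if (length(counts)) {
    if (is.null(names(counts)) || !all(grepl("^[ACGT]{5}$", names(counts))))
      stopf("counts must be named by ACGT 5-mers")
    if (any(counts < 0)) stopf("counts must be non-negative")
  }
  counts <- counts[counts > 0]
  if (length(counts)) counts <- counts[order(names(counts))]
  structure(list(counts = counts, n_total = sum(counts),
                 empty = length(counts) == 0L,
                 provenance = list(n_input = sum(counts)),
                 metadata = list(sample_id = sample_id,
                                 weighting = "per-read")),
            class = "pam_count_table")
}

#' @export
print.pam_count_table <- function(x, ...) {
  cat("PAM 5-mer count table:", length(x$counts), "distinct 5-mers,",
      x$n_total, "reads\n")
  invisible(x)
}

#' Write / read a PAM count table as TSV
#'
#' @param table A `pam_count_table`.
#' @param path Output TSV (columns pam, count).
#' @export
write_pam_counts_tsv <- function(table, path) {
  stopifnot(inherits(table, "pam_count_table"))
  write.table(data.frame(pam = names(table$counts),
                         count = as.integer(table$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_pam_counts_tsv
#' @export
read_pam_counts_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  pam_count_table(setNames(as.integer(d$count), d$pam))
}
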