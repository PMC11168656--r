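#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment
#'   nucleotideSubstitutionMatrix nmatch nmismatch mismatchTable
#'   reverseComplement indel pattern subject readDNAStringSet
#'   writeXStringSet
#' @importFrom IRanges IRanges
#' @importFrom methods is
NULL

default_aln_params <- function() {
  list(match = 5, mismatch = -4, gap_open = 10, gap_extend = 1,
       min_identity = 0.8)
}

#' Globally align amplicon reads to a reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties (match +5,
#' mismatch -4, gap open -10, gap extend -1 by default — standard
#' amplicon-calling parameters). When `orient = TRUE` each read is also
#' aligned as its reverse complement and the better-scoring orientation is
#' kept. Alignment is deterministic for fixed parameters; gap placement in
#' ambiguous runs follows the aligner's fixed tie-breaking.
#'
#' @param reads Character vector of read sequences (ACGT).
#' @param reference Reference sequence (character) or an
#'   `amplicon_reference`.
#' @param params List of alignment parameters, see `default_aln_params()`;
#'   `min_identity` is the identity threshold (computed over aligned,
#'   non-gap columns) below which a read is reported unalignable.
#' @param orient Detect and correct read orientation.
#' @param read_ids Optional read identifiers.
#' @return An object of class `amplicon_alignments` holding per-read
#'   scores, identities, strands, and indel operations in reference
#'   coordinates.
#' @export
align_reads <- function(reads, reference, params = list(), orient = TRUE,
                        read_ids = NULL) {
  params <- modifyList(default_aln_params(), params)
  refseq <- if (inherits(reference, "amplicon_reference"))
    reference$sequence else reference
  if (!is_dna(refseq)) stopf("reference must be a plain ACGT string")
  n <- length(reads)
  if (n == 0L) stopf("no reads to align")
  if (is.null(read_ids)) read_ids <- sprintf("read%06d", seq_len(n))
  if (any(!grepl("^[ACGTN]+$", reads)))
    stopf("reads must be non-empty strings over ACGTN")
  sm <- nucleotideSubstitutionMatrix(match = params$match,
                                     mismatch = params$mismatch)
  subj <- DNAString(refseq)
  strand <- rep("+", n)
  oriented <- reads
  if (orient) {
    fwd <- pairwiseAlignment(DNAStringSet(reads), subj, type = "global",
                             substitutionMatrix = sm,
                             gapOpening = params$gap_open,
                             gapExtension = params$gap_extend,
                             scoreOnly = TRUE)
    rc <- as.character(reverseComplement(DNAStringSet(reads)))
    rev <- pairwiseAlignment(DNAStringSet(rc), subj, type = "global",
                             substitutionMatrix = sm,
                             gapOpening = params$gap_open,
                             gapExtension = params$gap_extend,
                             scoreOnly = TRUE)
    flip <- rev > fwd
    strand[flip] <- "-"
    oriented[flip] <- rc[flip]
  }
  aln <- pairwiseAlignment(DNAStringSet(oriented), subj, type = "global",
                           substitutionMatrix = sm,
                           gapOpening = params$gap_open,
                           gapExtension = params$gap_extend)
  nm <- nmatch(aln)
  nmm <- nmismatch(aln)
  identity <- ifelse(nm + nmm > 0, nm / (nm + nmm), 0)
  dels <- as.list(indel(pattern(aln)))  # gaps in the read  = deletions
  inss <- as.list(indel(subject(aln)))  # gaps in the ref   = insertions
  # the indel() accessors omit terminal gaps; reads whose gap widths do
  # not account for the alignment length get the exact (slower) treatment
  alnlen <- methods::getGeneric("nchar")(aln)
  delw <- vapply(dels, function(r) sum(IRanges::width(r)), numeric(1))
  insw <- vapply(inss, function(r) sum(IRanges::width(r)), numeric(1))
  suspicious <- which(alnlen != nchar(oriented) + delw |
                        alnlen != nchar(refseq) + insw)
  for (i in suspicious) {
    p <- as.character(Biostrings::alignedPattern(aln[i]))
    s <- as.character(Biostrings::alignedSubject(aln[i]))
    dels[[i]] <- gap_ranges(p)
    inss[[i]] <- gap_ranges(s)
  }
  mm <- mismatchTable(aln)
  structure(list(
    read_ids = read_ids, reads = oriented, strand = strand,
    score = as.numeric(Biostrings::score(aln)),
    identity = as.numeric(identity),
    ops = extract_ops(dels, inss, n),
    mismatches = mm[, c("PatternId", "SubjectStart", "PatternSubstring")],
    reference = refseq, params = params, n = n
  ), class = "amplicon_alignments")
}

#' @rdname align_reads
#' @param read A single read sequence.
#' @export
align_read <- function(read, reference, params = list(), orient = TRUE) {
  align_reads(read, reference, params = params, orient = orient)
}

# All gap runs ("-"+) of an aligned string, as IRanges in column space.
gap_ranges <- function(aligned) {
  m <- gregexpr("-+", aligned)[[1]]
  if (m[1] == -1L) return(IRanges::IRanges())
  IRanges::IRanges(start = as.integer(m),
                   width = attr(m, "match.length"))
}

# Convert per-read gap ranges (alignment-column space) into reference
# coordinates. Returns a list of data.frames (op, ref_start, len): for "D"
# ref_start is the first deleted reference base (1-based); for "I" it is
# the reference base after which the insertion sits (0 = before base 1).
extract_ops <- function(dels, inss, n) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dels[[i]]
    ins <- inss[[i]]
    istarts <- IRanges::start(ins); iw <- IRanges::width(ins)
    ops <- list()
    if (length(d)) {
      ds <- IRanges::start(d); dw <- IRanges::width(d)
      before <- vapply(ds, function(s) sum(iw[istarts < s]), numeric(1))
      ops[[1L]] <- data.frame(op = "D", ref_start = ds - before, len = dw)
    }
    if (length(ins)) {
      before <- vapply(istarts, function(s)
        sum(iw[istarts < s & istarts != s]), numeric(1))
      ops[[length(ops) + 1L]] <-
        data.frame(op = "I", ref_start = istarts - 1L - before, len = iw)
    }
    out[[i]] <- if (length(ops)) {
      o <- do.call(rbind, ops)
      o[order(o$ref_start), , drop = FALSE]
    } else data.frame(op = character(0), ref_start = integer(0),
                      len = integer(0))
  }
  out
}

#' @export
print.amplicon_alignments <- function(x, ...) {
  cat("Global alignments of", x$n, "read(s) to a",
      nchar(x$reference), "nt reference\n")
  cat("  mean identity:", round(mean(x$identity), 4),
      "| minus-strand reads:", sum(x$strand == "-"), "\n")
  invisible(x)
}
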