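#' Write simulated reads to FASTA or FASTQ
#'
#' FASTQ qualities are a constant high Phred score (Sanger Phred+33):
#' simulated noise is controlled by the substitution-error parameter of the
#' generators, not by a quality model.
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `read` column (e.g. from [simulate_editing()]).
#' @param path Output file; format chosen by `format`.
#' @param format "fasta" or "fastq".
#' @param ids Read identifiers (default read000001, ...).
#' @return Invisibly, `path`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq"),
                        ids = NULL) {
  format <- match.arg(format)
  if (is.data.frame(reads)) {
    if (is.null(ids) && "read_id" %in% names(reads)) ids <- reads$read_id
    reads <- reads$read
  }
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  x <- DNAStringSet(reads)
  names(x) <- ids
  if (format == "fasta") {
    writeXStringSet(x, path)
  } else {
    q <- Biostrings::BStringSet(strrep("I", nchar(reads)))  # Phred 40
    writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Read amplicon/reporter reads from FASTA or FASTQ
#'
#' @param path Input file; format inferred from the extension
#'   (.fq/.fastq = FASTQ, otherwise FASTA).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a simulation truth table as TSV
#'
#' @param truth Data.frame of per-read truth (any generator output).
#' @param path Output TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Cas12a ortholog table
#'
#' The panel of 14 Cas12a orthologs screened for activity, as printed:
#' name, NCBI protein accession, host strain, protein length (aa) and
#' percent identity to LbCas12a.
#'
#' @return Data.frame with columns `name`, `accession`, `host`,
#'   `length_aa`, `identity_to_lb_pct`.
#' @export
cas12a_orthologs <- function() {
  path <- system.file("extdata", "cas12a_orthologs.tsv",
                      package = "cas12atk", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
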