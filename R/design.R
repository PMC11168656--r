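#' Configuration for the allele-specific crRNA designer
#'
#' Mb4Cas12a-F370A discriminates single-nucleotide mismatches at specific
#' PAM-proximal spacer positions; a guide is allele-specific when the SNV
#' falls at one of those positions. The designer scans both strands of the
#' variant's flanking sequence for PAM matches that place the SNV in this
#' window.
#'
#' @param pam_pattern IUPAC PAM, 5' of the protospacer (default `"YYN"`,
#'   Y = C/T, the degenerate Mb4Cas12a PAM).
#' @param window Mismatch-sensitive spacer positions, 1-based from the
#'   PAM-proximal end (default 1-2, 4-5, 7, 10, 13-18).
#' @param spacer_len Spacer length in nt (default 23).
#' @param flank Flanking sequence taken on each side of the variant
#'   (default 30 nt, giving a 61-nt window).
#' @return An object of class `designer_config`.
#' @export
designer_config <- function(pam_pattern = "YYN",
                            window = c(1, 2, 4, 5, 7, 10, 13:18),
                            spacer_len = 23L, flank = 30L) {
  pam_pattern <- toupper(pam_pattern)
  if (!nzchar(pam_pattern) ||
      !all(strsplit(pam_pattern, "")[[1]] %in% names(IUPAC)))
    stopf("pam_pattern must be a non-empty IUPAC string")
  window <- sort(unique(as.integer(window)))
  if (length(window) && (min(window) < 1L || max(window) > spacer_len))
    stopf("window positions must lie in 1..spacer_len")
  structure(list(pam_pattern = pam_pattern, window = window,
                 spacer_len = as.integer(spacer_len),
                 flank = as.integer(flank)),
            class = "designer_config")
}

#' Extract the variant-centred flanking window
#'
#' @param contig Contig sequence (character) holding the variant, or a
#'   named vector/list of contig sequences.
#' @param variant List or one-row data.frame with `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt`.
#' @param flank Bases to take on each side (default 30).
#' @return List: `window` (up to 2*flank+1 nt), `var_offset` (0-based
#'   offset of the variant within the window), `truncated` flag, and
#'   `window_start` (1-based contig coordinate of the window's first base).
#' @export
extract_flanks <- function(contig, variant, flank = 30L) {
  if (length(contig) > 1L || !is.null(names(contig))) {
    if (!variant$chrom %in% names(contig))
      stopf("contig '%s' not found in the supplied sequences",
            variant$chrom)
    contig <- contig[[variant$chrom]]
  }
  contig <- as.character(contig)
  pos <- as.integer(variant$pos)
  if (pos < 1L || pos > nchar(contig))
    stopf("variant %s: position %d outside contig", variant$id, pos)
  lo <- max(1L, pos - flank)
  hi <- min(nchar(contig), pos + flank)
  window <- substr(contig, lo, hi)
  center <- substr(contig, pos, pos)
  if (center != variant$ref)
    stopf("reference mismatch at %s:%d (%s): contig has %s, VCF ref %s",
          variant$chrom, pos, variant$id, center, variant$ref)
  list(window = window, var_offset = pos - lo,
       truncated = (pos - lo < flank) || (hi - pos < flank),
       window_start = lo)
}

iupac_regex <- function(pattern) {
  paste0(vapply(strsplit(pattern, "")[[1]], function(cd) {
    b <- IUPAC[[cd]]
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a variant window for allele-specific guide candidates
#'
#' On each strand, every PAM-pattern match immediately 5' of a full-length
#' protospacer lying inside the window yields a candidate iff the SNV falls
#' at a mismatch-sensitive spacer position (position 1 = PAM-proximal).
#' Candidates whose PAM overlaps the SNV are excluded (the SNV must sit in
#' the spacer, where a mismatch blocks cleavage). The emitted spacer
#' carries the targeted allele's base at the SNV position.
#'
#' @param window Variant-centred sequence from [extract_flanks()].
#' @param var_offset 0-based offset of the variant in `window`.
#' @param ref_base,alt_base The two alleles (plus-strand bases).
#' @param config A [designer_config()].
#' @param alleles Which allele(s) to target: `"alt"` (default; disrupt the
#'   pathogenic allele), `"ref"`, or `c("ref", "alt")`.
#' @param variant_id Identifier copied into the output.
#' @return Data.frame of candidates sorted by (strand, pam_start):
#'   `variant_id`, `strand`, `pam`, `pam_start` (0-based on the scanned
#'   strand: plus-strand coordinates for `+`, reverse-complement
#'   coordinates for `-`), `spacer`, `snv_spacer_position`,
#'   `targeted_allele`.
#' @export
scan_candidates <- function(window, var_offset, ref_base, alt_base, config,
                            alleles = "alt", variant_id = NA_character_) {
  stopifnot(inherits(config, "designer_config"))
  if (!all(alleles %in% c("ref", "alt")) || length(alleles) < 1L)
    stopf("alleles must be a subset of c('ref', 'alt')")
  if (var_offset < 0L || var_offset >= nchar(window))
    stopf("var_offset outside window")
  if (substr(window, var_offset + 1L, var_offset + 1L) != ref_base)
    stopf("window base at var_offset is not ref_base")
  P <- nchar(config$pam_pattern)
  L <- config$spacer_len
  strands <- list(
    `+` = list(seq = window, off = var_offset,
               ref = ref_base, alt = alt_base),
    `-` = list(seq = revcomp(window),
               off = nchar(window) - 1L - var_offset,
               ref = revcomp(ref_base), alt = revcomp(alt_base))
  )
  out <- list()
  rx <- iupac_regex(config$pam_pattern)
  for (sd in names(strands)) {
    s <- strands[[sd]]
    wlen <- nchar(s$seq)
    if (wlen < P + L) next
    hits <- gregexpr(sprintf("(?=%s)", rx), s$seq, perl = TRUE)[[1]]
    hits <- hits[hits > 0L]
    for (h in hits) {                      # h = 1-based PAM start
      p1 <- h + P                          # 1-based protospacer start
      if (p1 + L - 1L > wlen) next
      snv_pos <- s$off + 1L - p1 + 1L      # spacer position of the SNV
      if (!(snv_pos %in% config$window)) next
      proto <- substr(s$seq, p1, p1 + L - 1L)
      for (al in alleles) {
        spacer <- proto
        substr(spacer, snv_pos, snv_pos) <- s[[al]]
        out[[length(out) + 1L]] <- data.frame(
          variant_id = variant_id, strand = sd,
          pam = substr(s$seq, h, h + P - 1L), pam_start = h - 1L,
          spacer = spacer, snv_spacer_position = snv_pos,
          targeted_allele = al, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(variant_id = character(0), strand = character(0),
                      pam = character(0), pam_start = integer(0),
                      spacer = character(0),
                      snv_spacer_position = integer(0),
                      targeted_allele = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$strand, res$pam_start, res$targeted_allele), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Reference implementation of the window scan: explicit per-offset loops
# and a local IUPAC table, sharing no code with scan_candidates(). Used to
# validate the scanner.
scan_candidates_bruteforce <- function(window, var_offset, ref_base,
                                       alt_base, config, alleles = "alt",
                                       variant_id = NA_character_) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                Y = c("C", "T"), R = c("A", "G"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  pat <- strsplit(config$pam_pattern, "")[[1]]
  P <- length(pat)
  L <- config$spacer_len
  rows <- list()
  for (sd in c("+", "-")) {
    if (sd == "+") {
      chars <- strsplit(window, "")[[1]]
      off <- var_offset
      ref_b <- ref_base; alt_b <- alt_base
    } else {
      chars <- rev(unname(comp[strsplit(window, "")[[1]]]))
      off <- nchar(window) - 1L - var_offset
      ref_b <- unname(comp[ref_base]); alt_b <- unname(comp[alt_base])
    }
    wlen <- length(chars)
    for (h in seq_len(max(wlen - P + 1L, 0L))) {
      pam_ok <- TRUE
      for (k in seq_len(P))
        if (!(chars[h + k - 1L] %in% iupac[[pat[k]]])) { pam_ok <- FALSE
                                                         break }
      if (!pam_ok) next
      p1 <- h + P
      if (p1 + L - 1L > wlen) next
      snv_pos <- off + 1L - p1 + 1L
      if (!(snv_pos %in% config$window)) next
      for (al in alleles) {
        sp <- chars[p1:(p1 + L - 1L)]
        sp[snv_pos] <- if (al == "ref") ref_b else alt_b
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = variant_id, strand = sd,
          pam = paste(chars[h:(h + P - 1L)], collapse = ""),
          pam_start = h - 1L, spacer = paste(sp, collapse = ""),
          snv_spacer_position = snv_pos, targeted_allele = al,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(variant_id = character(0), strand = character(0),
                      pam = character(0), pam_start = integer(0),
                      spacer = character(0),
                      snv_spacer_position = integer(0),
                      targeted_allele = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$strand, res$pam_start, res$targeted_allele), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Design allele-specific guides for a batch of SNVs
#'
#' For every SNV, extracts the variant-centred flanks from the genome and
#' scans both strands for PAM placements that put the SNV in the
#' mismatch-sensitive spacer window. A variant is targetable iff at least
#' one candidate exists. Non-SNV records (indels, MNVs) are skipped and
#' counted; multi-allelic records are split.
#'
#' @param variants Path to a VCF file (read via the vcfR package), or a
#'   data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param genome Path to a FASTA file, a named character vector of contig
#'   sequences, or a `Biostrings::DNAStringSet`.
#' @param config A [designer_config()].
#' @param alleles Targeted allele(s), see [scan_candidates()].
#' @return List: `candidates` (one row per guide, with `chrom`/`pos`
#'   columns), `variants` (per-variant targetability flags) and `summary`
#'   (counts: records read, SNVs scanned, skipped, targetable).
#' @export
design_batch <- function(variants, genome, config = designer_config(),
                         alleles = "alt") {
  vars <- read_variants(variants)
  genome <- read_genome(genome)
  n_records <- attr(vars, "n_records")
  cands <- list()
  targetable <- logical(nrow(vars))
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    fl <- extract_flanks(genome, v, flank = config$flank)
    cc <- scan_candidates(fl$window, fl$var_offset, v$ref, v$alt, config,
                          alleles = alleles, variant_id = v$id)
    targetable[i] <- nrow(cc) > 0L
    if (nrow(cc)) {
      cc$chrom <- v$chrom
      cc$pos <- v$pos
      cands[[length(cands) + 1L]] <- cc
    }
  }
  candidates <- if (length(cands)) do.call(rbind, cands) else
    cbind(scan_candidates("A", 0L, "A", "C",
                          designer_config(window = integer(0))),
          data.frame(chrom = character(0), pos = integer(0)))
  cols <- c("variant_id", "chrom", "pos", "strand", "pam", "pam_start",
            "spacer", "snv_spacer_position", "targeted_allele")
  candidates <- candidates[, cols, drop = FALSE]
  rownames(candidates) <- NULL
  vars$targetable <- targetable
  list(candidates = candidates, variants = vars,
       summary = list(n_records = n_records, n_snv = nrow(vars),
                      n_skipped = attr(vars, "n_skipped"),
                      n_targetable = sum(targetable),
                      frac_targetable = if (nrow(vars)) mean(targetable)
                                        else NA_real_))
}

read_variants <- function(variants) {
  if (is.character(variants) && length(variants) == 1L) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stopf("reading VCF files requires the vcfR package")
    v <- vcfR::read.vcfR(variants, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    vars <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       id = fix$ID, ref = fix$REF, alt = fix$ALT,
                       stringsAsFactors = FALSE)
  } else {
    vars <- as.data.frame(variants, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "id", "ref", "alt")
    if (!all(need %in% names(vars)))
      stopf("variant table needs columns: %s", paste(need, collapse = ", "))
  }
  n_records <- nrow(vars)
  # split multi-allelic ALT fields, remembering the source record
  alts <- strsplit(vars$alt, ",", fixed = TRUE)
  record <- rep(seq_len(nrow(vars)), lengths(alts))
  vars <- vars[record, , drop = FALSE]
  vars$alt <- unlist(alts)
  # SNVs only; a record is "skipped" when none of its alleles is an SNV
  keep <- nchar(vars$ref) == 1L & nchar(vars$alt) == 1L &
    vars$ref %in% DNA_BASES & vars$alt %in% DNA_BASES &
    vars$ref != vars$alt
  n_skipped <- n_records - length(unique(record[keep]))
  vars <- vars[keep, , drop = FALSE]
  rownames(vars) <- NULL
  vars$id <- ifelse(is.na(vars$id) | vars$id == ".",
                    paste0(vars$chrom, ":", vars$pos), vars$id)
  attr(vars, "n_records") <- n_records
  attr(vars, "n_skipped") <- n_skipped
  vars
}

read_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readDNAStringSet(genome)
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(genome) || is.list(genome)) return(genome)
  stopf("genome must be a FASTA path, named character vector or DNAStringSet")
}

#' Write a guide candidate table to TSV
#'
#' @param batch Result of [design_batch()].
#' @param path Output TSV path.
#' @export
write_guides_tsv <- function(batch, path) {
  write.table(batch$candidates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
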