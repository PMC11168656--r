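#' GFP-activation reporter construct
#'
#' Describes the reporter insert used to read out Cas12a activity: a 5-nt
#' random PAM region followed by a 24-bp protospacer, placed between two
#' 20-nt homology arms immediately downstream of the GFP start codon. The
#' 29-nt insert (29 mod 3 = 2) knocks GFP out of frame; editing that changes
#' the insert length by a net +1 mod 3 restores the reading frame and turns
#' GFP on.
#'
#' @param upstream_homology 20-nt arm ending in the GFP ATG.
#' @param random_region 5-nt randomized PAM region ("NNNNN" in the template;
#'   a concrete library member carries ACGT bases).
#' @param protospacer 24-bp target sequence.
#' @param downstream_homology 20-nt arm at the start of the GFP body.
#' @return An object of class `reporter_construct`.
#' @examples
#' rc <- reporter_construct(random_region = "TTTAC")
#' render_amplicon(rc)
#' @export
reporter_construct <- function(upstream_homology = "AAGCCTTGTTTGCCACCATG",
                               random_region = "NNNNN",
                               protospacer = "GGATATGTTGAAGAACACCATGAC",
                               downstream_homology = "GTGAGCAAGGGCGAGGAGCT") {
  if (nchar(random_region) != 5L)
    stopf("random_region must be 5 nt (got %d)", nchar(random_region))
  if (nchar(protospacer) != 24L)
    stopf("protospacer must be 24 nt (got %d)", nchar(protospacer))
  if (!grepl("^[ACGTN]{5}$", random_region))
    stopf("random_region must be over ACGTN")
  if (!is_dna(protospacer) || !is_dna(upstream_homology) ||
      !is_dna(downstream_homology))
    stopf("homology arms and protospacer must be plain ACGT strings")
  x <- list(
    upstream_homology = upstream_homology,
    upstream_anchor = substr(upstream_homology,
                             nchar(upstream_homology) - 14L,
                             nchar(upstream_homology)),
    random_region = random_region,
    protospacer = protospacer,
    downstream_homology = downstream_homology,
    insert_len = nchar(random_region) + nchar(protospacer)
  )
  stopifnot(x$insert_len %% 3L == 2L)
  class(x) <- "reporter_construct"
  x
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat("Reporter construct (", x$insert_len, "-nt insert, out of frame)\n",
      sep = "")
  cat("  ", x$upstream_homology, "[", x$random_region, "|", x$protospacer,
      "]", x$downstream_homology, "\n", sep = "")
  invisible(x)
}

#' Render the full reporter amplicon
#'
#' Concatenates upstream homology, random region, protospacer and downstream
#' homology into the sequenced amplicon. For a library, returns one string
#' per member.
#'
#' @param x A `reporter_construct` or `reporter_library`.
#' @return Character vector of amplicon sequences.
#' @export
render_amplicon <- function(x) UseMethod("render_amplicon")

#' @export
render_amplicon.reporter_construct <- function(x) {
  paste0(x$upstream_homology, x$random_region, x$protospacer,
         x$downstream_homology)
}

#' @export
render_amplicon.reporter_library <- function(x) {
  d <- x$design
  paste0(d$upstream_homology, x$random_region, d$protospacer,
         d$downstream_homology)
}

# 0-based start of the insert within the rendered amplicon
insert_start <- function(design) nchar(design$upstream_homology)

#' Per-position PAM activity model
#'
#' Cleavage activity of a PAM is modelled as the product over positions
#' -5..-1 (position -1 immediately 5' of the protospacer) of per-base
#' factors in \[0, 1\]. A factor of 0 at any position forbids cleavage;
#' all-1 factors give full activity.
#'
#' @param weights 4 x 5 numeric matrix, rows A/C/G/T, columns positions
#'   -5..-1, entries in \[0, 1\].
#' @return An object of class `pam_activity_model`.
#' @seealso [pam_model_from_iupac()] for the common all-or-none case.
#' @export
pam_activity_model <- function(weights) {
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(4L, 5L)))
    stopf("weights must be a 4 x 5 matrix (bases x positions -5..-1)")
  if (any(weights < 0 | weights > 1))
    stopf("activity factors must lie in [0, 1]")
  rownames(weights) <- DNA_BASES
  colnames(weights) <- as.character(-5:-1)
  structure(list(weights = weights), class = "pam_activity_model")
}

#' Build an all-or-none PAM model from an IUPAC pattern
#'
#' @param pattern 5-character IUPAC string read 5'->3' over positions
#'   -5..-1, e.g. `"NTTTV"` for a TTTV PAM with a free -5 position, or
#'   `"NNYYN"` for the degenerate YYN preference.
#' @return A `pam_activity_model` with factor 1 for allowed bases, 0
#'   otherwise.
#' @export
pam_model_from_iupac <- function(pattern) {
  if (nchar(pattern) != 5L) stopf("pattern must cover positions -5..-1")
  codes <- strsplit(toupper(pattern), "")[[1]]
  w <- matrix(0, 4, 5, dimnames = list(DNA_BASES, as.character(-5:-1)))
  for (j in seq_len(5L)) {
    allowed <- IUPAC[[codes[j]]]
    if (is.null(allowed)) stopf("unknown IUPAC code '%s'", codes[j])
    w[allowed, j] <- 1
  }
  pam_activity_model(w)
}

#' Activity of concrete PAM 5-mers under a model
#'
#' @param model A `pam_activity_model`.
#' @param pam Character vector of 5-mers over ACGT (positions -5..-1).
#' @return Numeric vector of activities in \[0, 1\].
#' @export
pam_activity <- function(model, pam) {
  stopifnot(inherits(model, "pam_activity_model"))
  bad <- !grepl("^[ACGT]{5}$", pam)
  if (any(bad)) stopf("PAMs must be 5-mers over ACGT")
  if (length(pam) == 0L) return(numeric(0))
  m <- do.call(rbind, strsplit(pam, ""))
  act <- rep(1, length(pam))
  for (j in seq_len(5L))
    act <- act * model$weights[cbind(match(m[, j], DNA_BASES), j)]
  act
}

#' Staggered-cut indel model
#'
#' Cas12a leaves a staggered double-strand break with a 5-nt 5' overhang:
#' the nontarget strand is cut `cut_offset_nontarget` nt into the
#' protospacer (counting from the PAM-proximal end) and the target strand
#' `overhang_len` nt further. Error-prone repair then produces a deletion
#' with probability `p_deletion`, an insertion with `p_insertion`, or
#' perfect re-ligation with the remainder; indel lengths are drawn from
#' truncated geometric distributions and indels are centred on the
#' nontarget-strand cut.
#'
#' @param cut_offset_nontarget Nontarget-strand cut position, nt 3' of the
#'   PAM (cut after protospacer position 18 by default).
#' @param overhang_len Length of the 5' overhang in nt (default 5).
#' @param p_deletion,p_insertion Repair outcome probabilities; their sum
#'   must not exceed 1, the remainder is perfect repair.
#' @param deletion_len_dist,insertion_len_dist Lists
#'   `list(name = "geometric", p = ..., max = ...)` giving the indel length
#'   distribution on `1..max`.
#' @return An object of class `indel_model`.
#' @export
indel_model <- function(cut_offset_nontarget = 18L,
                        overhang_len = 5L,
                        p_deletion = 0.7,
                        p_insertion = 0.3,
                        deletion_len_dist = list(name = "geometric",
                                                 p = 0.3, max = 20L),
                        insertion_len_dist = list(name = "geometric",
                                                  p = 0.6, max = 10L)) {
  check_prob(p_deletion, "p_deletion")
  check_prob(p_insertion, "p_insertion")
  if (p_deletion + p_insertion > 1)
    stopf("p_deletion + p_insertion must not exceed 1")
  if (overhang_len < 0L) stopf("overhang_len must be >= 0")
  structure(list(
    cut_offset_nontarget = as.integer(cut_offset_nontarget),
    cut_offset_target = as.integer(cut_offset_nontarget + overhang_len),
    overhang_len = as.integer(overhang_len),
    p_deletion = p_deletion,
    p_insertion = p_insertion,
    deletion_len_dist = deletion_len_dist,
    insertion_len_dist = insertion_len_dist
  ), class = "indel_model")
}

# Sample n indel lengths (>= 1) from a truncated length distribution.
sample_indel_len <- function(n, dist) {
  if (n == 0L) return(integer(0))
  if (!identical(dist$name, "geometric"))
    stopf("unsupported length distribution '%s'", dist$name)
  k <- seq_len(dist$max)
  pr <- stats::dgeom(k - 1L, prob = dist$p)
  sample(k, n, replace = TRUE, prob = pr / sum(pr))
}
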