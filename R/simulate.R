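#' Draw a randomized-PAM reporter library
#'
#' Samples `n` library members from a reporter template: every member shares
#' the homology arms and protospacer and carries an independent uniform
#' random 5-mer in the PAM region.
#'
#' @param n Number of library members (>= 0).
#' @param design A `reporter_construct` template.
#' @param seed Integer seed; the same seed reproduces the library exactly.
#' @return A `reporter_library`: the shared design plus a character vector
#'   of 5-nt random regions. `length()` gives the member count and
#'   `render_amplicon()` the full sequences.
#' @export
make_library <- function(n, design = reporter_construct(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stopf("n must be a single non-negative number")
  stopifnot(inherits(design, "reporter_construct"))
  n <- as.integer(n)
  rr <- with_seed(seed, random_dna(n, 5L))
  structure(list(design = design, random_region = rr),
            class = "reporter_library")
}

#' @export
length.reporter_library <- function(x) length(x$random_region)

#' Materialise one library member as a reporter_construct
#'
#' @param lib A `reporter_library`.
#' @param i Member index.
#' @return A `reporter_construct` with that member's random region.
#' @export
library_member <- function(lib, i) {
  stopifnot(inherits(lib, "reporter_library"))
  d <- lib$design
  reporter_construct(d$upstream_homology, lib$random_region[[i]],
                     d$protospacer, d$downstream_homology)
}

#' Simulate PAM-dependent editing of reporter constructs
#'
#' Each construct is cut with probability `edit_prob` times the activity of
#' its PAM (the 5-mer in the random region, positions -5..-1). A cut is
#' repaired as a deletion or insertion per the indel model, centred on the
#' nontarget-strand cut position, or perfectly re-ligated; only reads that
#' acquire an indel are flagged edited.
#'
#' @param x A `reporter_library` or single `reporter_construct`.
#' @param pam_model A `pam_activity_model`.
#' @param imodel An `indel_model`.
#' @param edit_prob Editing probability for a fully active PAM.
#' @param seed Integer seed.
#' @return A data.frame with one row per construct: `read` (the edited
#'   amplicon sequence), `random_region`, `edited` (logical truth flag) and
#'   `net_delta` (signed length change in nt). The reporter design is
#'   attached as attribute `"design"`.
#' @export
simulate_editing <- function(x, pam_model, imodel = indel_model(),
                             edit_prob = 0.8, seed = NULL) {
  if (inherits(x, "reporter_construct")) {
    lib <- structure(list(design = x, random_region = x$random_region),
                     class = "reporter_library")
    if (grepl("N", x$random_region))
      stopf("construct random_region must be concrete ACGT, not '%s'",
            x$random_region)
    x <- lib
  }
  stopifnot(inherits(x, "reporter_library"),
            inherits(pam_model, "pam_activity_model"),
            inherits(imodel, "indel_model"))
  check_prob(edit_prob, "edit_prob")
  design <- x$design
  n <- length(x)
  amplicon <- render_amplicon(x)
  # 0-based boundary of the nontarget-strand cut within the amplicon
  cut <- insert_start(design) + 5L + imodel$cut_offset_nontarget

  res <- with_seed(seed, {
    act <- pam_activity(pam_model, x$random_region)
    cut_happens <- runif(n) < edit_prob * act
    u <- runif(n)
    type <- rep("none", n)
    type[cut_happens & u < imodel$p_deletion] <- "del"
    type[cut_happens & u >= imodel$p_deletion &
           u < imodel$p_deletion + imodel$p_insertion] <- "ins"
    len <- integer(n)
    is_del <- type == "del"
    is_ins <- type == "ins"
    len[is_del] <- sample_indel_len(sum(is_del), imodel$deletion_len_dist)
    len[is_ins] <- sample_indel_len(sum(is_ins), imodel$insertion_len_dist)
    ins_seq <- character(n)
    ins_seq[is_ins] <- random_dna(sum(is_ins),
                                  max(len[is_ins], 1L))  # over-draw, trim
    ins_seq[is_ins] <- substr(ins_seq[is_ins], 1L, len[is_ins])
    list(type = type, len = len, ins_seq = ins_seq)
  })

  read <- amplicon
  net_delta <- integer(n)
  amp_len <- nchar(amplicon)
  is_del <- res$type == "del"
  if (any(is_del)) {
    L <- res$len[is_del]
    # delete [start0, start0 + L) centred on the cut, clipped into the read
    start0 <- pmax(1L, pmin(cut - L %/% 2L, amp_len[is_del] - L - 1L))
    read[is_del] <- paste0(substr(amplicon[is_del], 1L, start0),
                           substr(amplicon[is_del], start0 + L + 1L,
                                  amp_len[is_del]))
    net_delta[is_del] <- -L
  }
  is_ins <- res$type == "ins"
  if (any(is_ins)) {
    read[is_ins] <- paste0(substr(amplicon[is_ins], 1L, cut),
                           res$ins_seq[is_ins],
                           substr(amplicon[is_ins], cut + 1L,
                                  amp_len[is_ins]))
    net_delta[is_ins] <- res$len[is_ins]
  }

  out <- data.frame(read = read, random_region = x$random_region,
                    edited = res$type != "none", net_delta = net_delta,
                    stringsAsFactors = FALSE)
  attr(out, "design") <- design
  out
}

#' GFP selection of an edited reporter pool
#'
#' Models fluorescence sorting: a cell turns GFP-positive iff its reporter
#' was edited and the 29-nt insert length was restored to frame,
#' (29 + net_delta) mod 3 = 0. Selection keeps exactly those reads, plus a
#' `leak_rate` fraction of all other reads (sorting impurity), in an order
#' shuffled deterministically by `seed`.
#'
#' @param pool Data.frame from [simulate_editing()] (columns `read`,
#'   `edited`, `net_delta`).
#' @param leak_rate Probability that a non-fluorescent cell contaminates the
#'   sorted pool.
#' @param seed Integer seed.
#' @return The retained rows of `pool`, shuffled; design attribute kept.
#' @export
simulate_gfp_pool <- function(pool, leak_rate = 0, seed = NULL) {
  check_prob(leak_rate, "leak_rate")
  stopifnot(is.data.frame(pool),
            all(c("read", "edited", "net_delta") %in% names(pool)))
  design <- attr(pool, "design")
  insert_len <- if (!is.null(design)) design$insert_len else 29L
  green <- pool$edited & (insert_len + pool$net_delta) %% 3L == 0L
  out <- with_seed(seed, {
    leak <- !green & runif(nrow(pool)) < leak_rate
    kept <- pool[green | leak, , drop = FALSE]
    kept[sample(nrow(kept)), , drop = FALSE]
  })
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

#' Specification of a biallelic amplicon sequencing experiment
#'
#' Describes a heterozygous SNV locus for simulation: reads are drawn from
#' the ref or alt allele, each allele is edited (indel at the cut site) at
#' its own rate, and uniform substitution errors model sequencing noise.
#' This is the test bed for allele-resolved indel quantification.
#'
#' @param reference Amplicon reference sequence (ref allele).
#' @param snp_offset 0-based offset of the SNV in `reference`.
#' @param ref_base,alt_base The two alleles (single, distinct ACGT bases);
#'   `reference[snp_offset]` must equal `ref_base`.
#' @param allele_fraction_alt Fraction of reads from the alt allele.
#' @param indel_rate_ref,indel_rate_alt Per-allele editing rates.
#' @param n_reads Number of reads.
#' @param substitution_error_rate Per-base substitution error rate.
#' @param cut_site 0-based cut boundary where simulated indels are centred;
#'   defaults to the middle of the reference.
#' @param imodel `indel_model` supplying indel type/length distributions.
#' @param seed Integer seed.
#' @return An object of class `allele_amplicon_spec`.
#' @export
allele_amplicon_spec <- function(reference, snp_offset, ref_base, alt_base,
                                 allele_fraction_alt = 0.5,
                                 indel_rate_ref = 0, indel_rate_alt = 0,
                                 n_reads = 1000L,
                                 substitution_error_rate = 0,
                                 cut_site = NULL,
                                 imodel = indel_model(),
                                 seed = NULL) {
  if (!is_dna(reference)) stopf("reference must be a plain ACGT string")
  if (snp_offset < 0 || snp_offset >= nchar(reference))
    stopf("snp_offset out of range")
  if (ref_base == alt_base) stopf("ref_base and alt_base must differ")
  if (substr(reference, snp_offset + 1L, snp_offset + 1L) != ref_base)
    stopf("reference[snp_offset] is not ref_base")
  check_prob(allele_fraction_alt, "allele_fraction_alt")
  check_prob(indel_rate_ref, "indel_rate_ref")
  check_prob(indel_rate_alt, "indel_rate_alt")
  check_prob(substitution_error_rate, "substitution_error_rate")
  if (is.null(cut_site)) cut_site <- nchar(reference) %/% 2L
  structure(list(reference = reference, snp_offset = as.integer(snp_offset),
                 ref_base = ref_base, alt_base = alt_base,
                 allele_fraction_alt = allele_fraction_alt,
                 indel_rate_ref = indel_rate_ref,
                 indel_rate_alt = indel_rate_alt,
                 n_reads = as.integer(n_reads),
                 substitution_error_rate = substitution_error_rate,
                 cut_site = as.integer(cut_site), imodel = imodel,
                 seed = seed),
            class = "allele_amplicon_spec")
}

#' Simulate reads from a biallelic amplicon
#'
#' @param spec An [allele_amplicon_spec()].
#' @return Data.frame with per-read truth: `read_id`, `read`, `allele`
#'   ("ref"/"alt"), `edited`, `net_delta`.
#' @export
simulate_allele_amplicons <- function(spec) {
  stopifnot(inherits(spec, "allele_amplicon_spec"))
  n <- spec$n_reads
  ref <- spec$reference
  alt_seq <- ref
  substr(alt_seq, spec$snp_offset + 1L, spec$snp_offset + 1L) <- spec$alt_base
  im <- spec$imodel

  with_seed(spec$seed, {
    allele <- ifelse(runif(n) < spec$allele_fraction_alt, "alt", "ref")
    base_seq <- ifelse(allele == "alt", alt_seq, ref)
    rate <- ifelse(allele == "alt", spec$indel_rate_alt, spec$indel_rate_ref)
    cut_happens <- runif(n) < rate
    u <- runif(n)
    p_d <- im$p_deletion / max(im$p_deletion + im$p_insertion, 1e-12)
    type <- rep("none", n)
    type[cut_happens & u < p_d] <- "del"
    type[cut_happens & u >= p_d] <- "ins"
    len <- integer(n)
    len[type == "del"] <- sample_indel_len(sum(type == "del"),
                                           im$deletion_len_dist)
    len[type == "ins"] <- sample_indel_len(sum(type == "ins"),
                                           im$insertion_len_dist)
    read <- base_seq
    net_delta <- integer(n)
    cut <- spec$cut_site
    reflen <- nchar(ref)
    i_del <- which(type == "del")
    for (i in i_del) {
      L <- len[i]
      s0 <- max(1L, min(cut - L %/% 2L, reflen - L - 1L))
      read[i] <- paste0(substr(base_seq[i], 1L, s0),
                        substr(base_seq[i], s0 + L + 1L, reflen))
      net_delta[i] <- -L
    }
    i_ins <- which(type == "ins")
    for (i in i_ins) {
      L <- len[i]
      read[i] <- paste0(substr(base_seq[i], 1L, cut),
                        paste(sample(DNA_BASES, L, TRUE), collapse = ""),
                        substr(base_seq[i], cut + 1L, reflen))
      net_delta[i] <- L
    }
    if (spec$substitution_error_rate > 0 && n > 0L) {
      read <- vapply(read, function(s) {
        b <- strsplit(s, "")[[1]]
        hit <- runif(length(b)) < spec$substitution_error_rate
        if (any(hit))
          b[hit] <- vapply(b[hit], function(cur)
            sample(setdiff(DNA_BASES, cur), 1L), character(1))
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    data.frame(read_id = sprintf("read%06d", seq_len(n)), read = read,
               allele = allele, edited = type != "none",
               net_delta = net_delta, stringsAsFactors = FALSE)
  })
}

#' Simulate gel lane intensities for a known cleaved fraction
#'
#' Constructs band intensities (a undigested, b and c products) whose
#' product fraction satisfies (b+c)/(a+b+c) = 1 - (1-f)^2, the relation a
#' double-cut substrate obeys when each strand is cleaved independently
#' with probability `f`. [quantify_cleavage()] then inverts the lanes back
#' to 100*f exactly.
#'
#' @param true_cleaved_fraction Cleaved fraction f in \[0, 1\].
#' @param total_intensity Total lane intensity a+b+c (> 0).
#' @param b_c_split Fraction of the product intensity assigned to band b.
#' @param label Lane label (PAM or temperature).
#' @return A [gel_lanes()] object.
#' @export
simulate_gel <- function(true_cleaved_fraction, total_intensity = 1,
                         b_c_split = 0.5, label = NA_character_) {
  check_prob(true_cleaved_fraction, "true_cleaved_fraction")
  check_prob(b_c_split, "b_c_split")
  if (total_intensity <= 0) stopf("total_intensity must be > 0")
  f <- true_cleaved_fraction
  prod <- total_intensity * (1 - (1 - f)^2)
  gel_lanes(a = total_intensity - prod, b = b_c_split * prod,
            c = (1 - b_c_split) * prod, label = label)
}
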