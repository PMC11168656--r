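test_that("designer config defaults encode the editing window", {
  cfg <- designer_config()
  expect_equal(cfg$pam_pattern, "YYN")
  expect_equal(cfg$window, c(1, 2, 4, 5, 7, 10, 13, 14, 15, 16, 17, 18))
  expect_equal(cfg$spacer_len, 23L)
  expect_equal(cfg$flank, 30L)
  expect_error(designer_config(window = c(0, 1)), "1..spacer_len")
  expect_error(designer_config(pam_pattern = "YXZ"), "IUPAC")
})

test_that("flank extraction centres the variant and checks the ref base", {
  contig <- withr::with_seed(53, rand_seq(200))
  rb <- substr(contig, 100, 100)
  v <- list(chrom = "chr1", pos = 100, id = "rs1", ref = rb,
            alt = setdiff(BASES, rb)[1])
  fl <- extract_flanks(setNames(contig, "chr1"), v)
  expect_equal(nchar(fl$window), 61L)
  expect_equal(fl$var_offset, 30L)
  expect_false(fl$truncated)
  expect_equal(substr(fl$window, 31, 31), rb)
  # 61-nt context passed directly comes back unchanged
  fl2 <- extract_flanks(fl$window, list(chrom = "x", pos = 31, id = "rs1",
                                        ref = rb, alt = v$alt))
  expect_equal(fl2$window, fl$window)
  # near a contig end the window truncates with a flag
  v10 <- list(chrom = "chr1", pos = 10, id = "rs2",
              ref = substr(contig, 10, 10), alt = "N")
  fl3 <- extract_flanks(setNames(contig, "chr1"), v10)
  expect_true(fl3$truncated)
  expect_equal(nchar(fl3$window), 40L)  # 9 upstream + variant + 30
  # reference mismatch errors name the site
  vbad <- list(chrom = "chr1", pos = 100, id = "rs3",
               ref = setdiff(BASES, rb)[1], alt = rb)
  expect_error(extract_flanks(setNames(contig, "chr1"), vbad),
               "reference mismatch at chr1:100")
})

test_that("a PAM directly 5' of the variant gives spacer position 1", {
  # ...TTA immediately 5' of the variant base, 23 nt of sequence 3' of it
  withr::with_seed(59, {
    left <- rand_seq(10)
    right <- rand_seq(22)
  })
  window <- paste0(left, "TTA", "G", right)
  var_off <- nchar(left) + 3L
  cand <- scan_candidates(window, var_off, "G", "A", designer_config())
  plus1 <- cand[cand$strand == "+" & cand$snv_spacer_position == 1, ]
  expect_equal(nrow(plus1), 1L)
  expect_equal(plus1$pam, "TTA")
  expect_equal(plus1$pam_start, 10L)
  expect_equal(substr(plus1$spacer, 1, 1), "A")  # targeted alt allele
  expect_equal(nchar(plus1$spacer), 23L)
  # empty mismatch window yields no candidates
  expect_equal(nrow(scan_candidates(window, var_off, "G", "A",
                                    designer_config(window = integer(0)))),
               0L)
})

test_that("scanner equals the brute-force reference on random windows", {
  withr::with_seed(61, {
    for (pat in c("YYN", "TTTV")) {
      cfg <- designer_config(pam_pattern = pat)
      for (i in 1:150) {
        w <- rand_seq(61)
        rb <- substr(w, 31, 31)
        ab <- sample(setdiff(BASES, rb), 1)
        got <- scan_candidates(w, 30, rb, ab, cfg, alleles = c("ref", "alt"))
        want <- cas12atk:::scan_candidates_bruteforce(
          w, 30, rb, ab, cfg, alleles = c("ref", "alt"))
        expect_identical(got, want)
      }
    }
  })
})

test_that("every candidate re-validates against its own rules", {
  cfg <- designer_config()
  withr::with_seed(67, {
    for (i in 1:40) {
      w <- rand_seq(61)
      rb <- substr(w, 31, 31)
      ab <- sample(setdiff(BASES, rb), 1)
      cand <- scan_candidates(w, 30, rb, ab, cfg)
      if (nrow(cand) == 0) next
      for (k in seq_len(nrow(cand))) {
        s <- if (cand$strand[k] == "+") w else
          cas12atk:::revcomp(w)
        pam <- substr(s, cand$pam_start[k] + 1, cand$pam_start[k] + 3)
        expect_equal(pam, cand$pam[k])
        expect_true(grepl("^[CT][CT][ACGT]$", pam))
        expect_true(cand$snv_spacer_position[k] %in% cfg$window)
        off <- if (cand$strand[k] == "+") 30 else 60 - 30
        expect_equal(cand$pam_start[k] + 3 + cand$snv_spacer_position[k],
                     off + 1)
        base <- substr(cand$spacer[k], cand$snv_spacer_position[k],
                       cand$snv_spacer_position[k])
        expected <- if (cand$strand[k] == "+") ab else
          cas12atk:::revcomp(ab)
        expect_equal(base, expected)
      }
    }
  })
})

test_that("strand symmetry and window monotonicity hold", {
  cfg <- designer_config()
  withr::with_seed(71, {
    for (i in 1:25) {
      w <- rand_seq(61)
      rb <- substr(w, 31, 31)
      ab <- sample(setdiff(BASES, rb), 1)
      a <- scan_candidates(w, 30, rb, ab, cfg)
      b <- scan_candidates(cas12atk:::revcomp(w), 30,
                           cas12atk:::revcomp(rb),
                           cas12atk:::revcomp(ab), cfg)
      # mirror image: strands swap, everything else matches
      a$strand <- chartr("+-", "-+", a$strand)
      a <- a[order(a$strand, a$pam_start), ]
      rownames(a) <- rownames(b) <- NULL
      expect_equal(a, b)
      # enlarging the window never removes candidates
      big <- designer_config(window = 1:18)
      cand_small <- scan_candidates(w, 30, rb, ab, cfg)
      cand_big <- scan_candidates(w, 30, rb, ab, big)
      key <- function(d) paste(d$strand, d$pam_start, d$targeted_allele)
      expect_true(all(key(cand_small) %in% key(cand_big)))
    }
  })
})

test_that("design_batch handles VCF-style input end to end", {
  withr::with_seed(73, {
    contig <- rand_seq(400)
  })
  genome <- setNames(contig, "chr1")
  pick <- c(100, 200, 300)
  vars <- data.frame(chrom = "chr1", pos = pick,
                     id = paste0("rs", pick),
                     ref = vapply(pick, function(p) substr(contig, p, p),
                                  character(1)),
                     alt = NA_character_, stringsAsFactors = FALSE)
  vars$alt <- vapply(vars$ref, function(b) setdiff(BASES, b)[1],
                     character(1))
  # add one indel record that must be skipped
  vars <- rbind(vars, data.frame(chrom = "chr1", pos = 150, id = "indel1",
                                 ref = substr(contig, 150, 151), alt = "A"))
  res <- design_batch(vars, genome)
  expect_equal(res$summary$n_records, 4L)
  expect_equal(res$summary$n_snv, 3L)
  expect_equal(res$summary$n_skipped, 1L)
  expect_equal(res$summary$n_targetable, sum(res$variants$targetable))
  expect_true(all(res$candidates$targeted_allele == "alt"))
  # per-variant candidates equal a direct window scan
  for (i in 1:3) {
    fl <- extract_flanks(genome, vars[i, ])
    direct <- scan_candidates(fl$window, fl$var_offset, vars$ref[i],
                              vars$alt[i], designer_config(),
                              variant_id = vars$id[i])
    expect_equal(nrow(res$candidates[res$candidates$variant_id ==
                                       vars$id[i], ]), nrow(direct))
  }
  # deterministic re-run
  expect_identical(res$candidates, design_batch(vars, genome)$candidates)
  # empty variant set
  res0 <- design_batch(vars[0, ], genome)
  expect_equal(nrow(res0$candidates), 0L)
  expect_equal(res0$summary$n_targetable, 0L)
  # missing contig errors by name
  vbad <- data.frame(chrom = "chrX", pos = 5, id = "x", ref = "A",
                     alt = "C")
  expect_error(design_batch(vbad, genome), "chrX")
})

test_that("VCF input is parsed, multi-allelics split, non-SNVs counted", {
  withr::with_seed(79, {
    contig <- rand_seq(300)
  })
  vcf <- withr::local_tempfile(fileext = ".vcf")
  p1 <- 100; p2 <- 180; p3 <- 240
  r1 <- substr(contig, p1, p1); r2 <- substr(contig, p2, p2)
  r3 <- substr(contig, p3, p3)
  a1 <- setdiff(BASES, r1)[1]
  a2 <- paste(setdiff(BASES, r2)[1:2], collapse = ",")  # multi-allelic
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("chr1\t%d\trsA\t%s\t%s\t.\t.\t.", p1, r1, a1),
    sprintf("chr1\t%d\trsB\t%s\t%s\t.\t.\t.", p2, r2, a2),
    sprintf("chr1\t%d\trsC\t%sA\tA\t.\t.\t.", p3, r3)), vcf)  # indel
  res <- design_batch(vcf, setNames(contig, "chr1"))
  expect_equal(res$summary$n_records, 3L)
  expect_equal(res$summary$n_snv, 3L)   # 1 + 2 split alleles
  expect_equal(res$summary$n_skipped, 1L)
  expect_equal(sum(res$variants$id == "rsB"), 2L)
  expect_false("rsC" %in% res$variants$id)
})

test_that("a variant with no correctly placed pyrimidine PAM is untargetable", {
  # an AC-repeat window has no pyrimidine dinucleotide on either strand
  # (plus: AC/CA only; minus: GT/TG only), so no YYN PAM can be placed
  w <- paste(rep(c("A", "C"), length.out = 61), collapse = "")
  expect_equal(substr(w, 31, 31), "A")
  cand <- scan_candidates(w, 30, "A", "G", designer_config())
  want <- cas12atk:::scan_candidates_bruteforce(w, 30, "A", "G",
                                                designer_config())
  expect_identical(cand, want)
  expect_equal(nrow(cand), 0L)
  res <- design_batch(data.frame(chrom = "c", pos = 31, id = "v1",
                                 ref = "A", alt = "G"),
                      setNames(w, "c"))
  expect_false(res$variants$targetable)
  expect_equal(res$summary$n_targetable, 0L)
})
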