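test_that("random-region extraction follows the printed anchors", {
  read <- paste0("AAGCCTTGTTTGCCACCATG", "TCAGT",
                 "GGATATGTTGAAGAACACCATGAC")
  ex <- extract_random_region(read)
  expect_equal(ex$pam, "TCAGT")
  expect_equal(ex$status, "ok")
  # missing upstream anchor
  expect_equal(extract_random_region("ACGTACGTACGT")$status,
               "no_upstream_anchor")
  # downstream anchor mismatch
  bad <- paste0("AAGCCTTGTTTGCCACCATG", "TCAGT", "CCATATGTT")
  expect_equal(extract_random_region(bad)$status, "downstream_mismatch")
  # non-ACGT base inside the 5-mer
  amb <- paste0("AAGCCTTGTTTGCCACCATG", "TCNGT", "GGATATG")
  expect_equal(extract_random_region(amb)$status, "non_acgt_base")
  # read ends inside the layout
  short <- paste0("AAGCCTTGTTTGCCACCATG", "TCA")
  expect_equal(extract_random_region(short)$status, "truncated")
  # one anchor mismatch tolerated only when requested
  mm <- paste0("AAGCCTAGTTTGCCACCATG", "TCAGT", "GGATATG")
  expect_equal(extract_random_region(mm)$status, "no_upstream_anchor")
  expect_equal(extract_random_region(mm, max_mismatch = 1)$pam, "TCAGT")
})

test_that("frame classification applies the 29+delta mod 3 rule", {
  rc <- reporter_construct(random_region = "TTTAC")
  amp <- render_amplicon(rc)
  # identical read
  cf <- classify_frame(amp, rc)
  expect_equal(cf$class, "unedited")
  expect_equal(cf$delta, 0L)
  # 2-nt deletion at the cut site: (29-2) mod 3 = 0 -> in frame
  del2 <- paste0(substr(amp, 1, 42), substr(amp, 45, 69))
  # 3-nt deletion: (29-3) mod 3 = 2 -> out of frame
  del3 <- paste0(substr(amp, 1, 42), substr(amp, 46, 69))
  # 1-nt insertion: (29+1) mod 3 = 0 -> in frame
  ins1 <- paste0(substr(amp, 1, 43), "A", substr(amp, 44, 69))
  # substitution only -> unedited
  sub1 <- amp; substr(sub1, 30, 30) <- "C"
  cf <- classify_frame(c(del2, del3, ins1, sub1), rc)
  expect_equal(cf$class, c("in_frame_edit", "out_of_frame_edit",
                           "in_frame_edit", "unedited"))
  expect_equal(cf$delta, c(-2L, -3L, 1L, 0L))
  # garbage read is unalignable
  cf <- classify_frame(rand_seq(69), rc)
  expect_equal(cf$class, "unalignable")
})

test_that("in-frame filter equals simulator truth at zero error", {
  sc <- simulate_screen(3000, pam_iupac = "NNNNN", seed = 51)
  cf <- classify_pool(sc$pool)
  truth_if <- sc$pool$edited & (29 + sc$pool$net_delta) %% 3 == 0
  expect_identical(cf$class == "in_frame_edit", truth_if)
  # delta agrees read-by-read on edited reads
  expect_equal(cf$delta, sc$pool$net_delta)
})

test_that("build_pam_counts filters and accounts for every read", {
  rc <- reporter_construct(random_region = "TTTAC")
  amp <- render_amplicon(rc)
  in_frame <- paste0(substr(amp, 1, 42), substr(amp, 45, 69))  # -2
  out_frame <- paste0(substr(amp, 1, 42), substr(amp, 46, 69)) # -3
  reads <- c(rep(in_frame, 4), rep(out_frame, 6))
  tab <- build_pam_counts(reads)
  expect_equal(unname(tab$counts["TTTAC"]), 4L)
  expect_equal(tab$n_total, 4L)
  expect_equal(tab$provenance$n_input, 10L)
  expect_equal(tab$provenance$out_of_frame_edit, 6L)
  # all rejected -> explicit empty table
  tab0 <- build_pam_counts(c("ACGT", "GGGG"))
  expect_true(tab0$empty)
  expect_equal(tab0$n_total, 0L)
  expect_error(compute_profile(tab0), "empty")
  expect_error(compute_wheel(tab0), "empty")
})

test_that("profile arithmetic matches the logo convention", {
  # two sequences differing at -1: 1 bit there, 2 bits elsewhere
  pr <- compute_profile(pam_count_table(c(TTTTA = 1, TTTTG = 1)))
  expect_equal(unname(pr$pfm[, "-1"]),
               c(0.5, 0, 0.5, 0))
  expect_equal(unname(pr$ic), c(2, 2, 2, 2, 1))
  expect_equal(colSums(pr$pfm), setNames(rep(1, 5), as.character(-5:-1)))
  # uniform counts over all 1024 5-mers -> 0 bits everywhere
  all5 <- do.call(paste0, expand.grid(BASES, BASES, BASES, BASES, BASES))
  pru <- compute_profile(pam_count_table(setNames(rep(1L, 1024), all5)))
  expect_equal(unname(pru$ic), rep(0, 5), tolerance = 1e-12)
  # a single 5-mer -> 2 bits everywhere (correction off)
  prs <- compute_profile(pam_count_table(c(TTTTC = 10)))
  expect_equal(unname(prs$ic), rep(2, 5))
  # small-sample correction subtracts 3/(2 ln2 n), floored at 0
  prc <- compute_profile(pam_count_table(c(TTTTC = 10)), correction = TRUE)
  expect_equal(unname(prc$ic), rep(2 - 3 / (2 * log(2) * 10), 5))
  pru_c <- compute_profile(pam_count_table(setNames(rep(1L, 1024), all5)),
                           correction = TRUE)
  expect_equal(unname(pru_c$ic), rep(0, 5))
})

test_that("baseline normalisation removes library composition bias", {
  # selected pool twice enriched for T at -1 relative to a biased input
  sel <- pam_count_table(c(TTTTT = 80, TTTTA = 20))
  base <- pam_count_table(c(TTTTT = 400, TTTTA = 100))
  pr <- compute_profile(sel, baseline = base)
  # identical composition -> flat after normalisation
  expect_equal(unname(pr$pfm["T", "-1"]), 0.5)
  expect_equal(unname(pr$pfm["A", "-1"]), 0.5)
})

test_that("PAM wheel wedges nest and conserve counts", {
  wh <- compute_wheel(pam_count_table(c(TTTTA = 3, TTTTG = 1)))
  inner <- wh$nodes[wh$nodes$depth == 1, ]
  expect_equal(inner$base, c("A", "G"))
  expect_equal(inner$end_deg - inner$start_deg, c(270, 90))
  # single 5-mer: one full wedge per ring
  wh1 <- compute_wheel(pam_count_table(c(CTTAC = 5)))
  expect_equal(nrow(wh1$nodes), 5L)
  expect_true(all(wh1$nodes$end_deg - wh1$nodes$start_deg == 360))
  # conservation on a random table
  withr::with_seed(17, {
    km <- unique(replicate(50, rand_seq(5)))
    tab <- pam_count_table(setNames(sample(1:20, length(km), TRUE), km))
  })
  wh <- compute_wheel(tab)
  nodes <- wh$nodes
  expect_equal(sum(nodes$count[nodes$depth == 1]), tab$n_total)
  for (d in 1:4) {
    parents <- nodes[nodes$depth == d, ]
    kids <- nodes[nodes$depth == d + 1, ]
    for (i in seq_len(nrow(parents))) {
      sel <- substr(kids$path, 1, d) == parents$path[i]
      expect_equal(sum(kids$count[sel]), parents$count[i])
      expect_equal(min(kids$start_deg[sel]), parents$start_deg[i])
      expect_equal(max(kids$end_deg[sel]), parents$end_deg[i])
      expect_equal(sum(kids$fraction[sel]), 1)
    }
  }
  # full ring sums to 360 degrees
  for (d in 1:5)
    expect_equal(sum(nodes$end_deg[nodes$depth == d] -
                       nodes$start_deg[nodes$depth == d]), 360)
})

test_that("profiles export to JSON/TSV/SVG and re-import losslessly", {
  tab <- pam_count_table(c(TTTAC = 30, CTTAC = 12, TTCAG = 5))
  pr <- compute_profile(tab)
  stem <- withr::local_tempfile()
  paths <- export_profile(pr, stem)
  expect_true(all(file.exists(paths)))
  back <- import_profile(paths[1])
  expect_equal(back$pfm, pr$pfm, tolerance = 1e-12)
  expect_equal(back$ic, pr$ic, tolerance = 1e-12)
  expect_equal(back$n, pr$n)
  # logo SVG has one column group per PAM position
  svg <- readLines(paths[3])
  for (p in -5:-1)
    expect_true(any(grepl(sprintf('id="pos%d"', p), svg)))
  # wheel SVG has one ring group per PAM position
  wstem <- withr::local_tempfile()
  wpaths <- export_profile(compute_wheel(tab), wstem)
  wsvg <- readLines(wpaths[3])
  for (p in -5:-1)
    expect_true(any(grepl(sprintf('id="ring%d"', p), wsvg)))
})
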