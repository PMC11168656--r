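# Independent oracles and fixture builders used across the suite.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(len) paste(sample(BASES, len, TRUE), collapse = "")

# Gotoh global alignment score with affine gaps (gap of length L costs
# open + L * ext). Pure-R dynamic program, independent of the package's
# alignment path.
gotoh_score <- function(read, ref, match = 5, mismatch = -4,
                        gap_open = 10, gap_ext = 1) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in ref (insertion in read)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in read (deletion)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Apply one known edit to a reference; returns the mutated read plus the
# expected indel class and net delta (the construction oracle).
apply_known_edit <- function(ref, type, pos = NULL, len = NULL) {
  n <- nchar(ref)
  switch(type,
    none = list(read = ref, class = "unedited", delta = 0L),
    sub = {
      if (is.null(pos)) pos <- sample(n, 1)
      cur <- substr(ref, pos, pos)
      read <- ref
      substr(read, pos, pos) <- sample(setdiff(BASES, cur), 1)
      list(read = read, class = "unedited", delta = 0L)
    },
    del = {
      if (is.null(len)) len <- sample(1:3, 1)
      if (is.null(pos)) pos <- sample(n - len, 1)
      list(read = paste0(substr(ref, 1, pos - 1), substr(ref, pos + len, n)),
           class = "deletion", delta = -len)
    },
    ins = {
      if (is.null(len)) len <- sample(1:3, 1)
      if (is.null(pos)) pos <- sample(n - 1, 1)
      list(read = paste0(substr(ref, 1, pos), rand_seq(len),
                         substr(ref, pos + 1, n)),
           class = "insertion", delta = len)
    })
}

# Small reporter pipeline fixture: library -> editing -> GFP selection.
simulate_screen <- function(n, pam_iupac = "NTTTV", seed = 1,
                            leak_rate = 0, edit_prob = 0.8) {
  lib <- make_library(n, seed = seed)
  pool <- simulate_editing(lib, pam_model_from_iupac(pam_iupac),
                           edit_prob = edit_prob, seed = seed + 1L)
  list(lib = lib, pool = pool,
       selected = simulate_gfp_pool(pool, leak_rate = leak_rate,
                                    seed = seed + 2L))
}

# Frame-classify a simulated pool against each read's own construct
# (grouped by random region so every group gets its rendered reference).
classify_pool <- function(pool, design = reporter_construct()) {
  out <- data.frame(class = rep(NA_character_, nrow(pool)),
                    delta = rep(NA_integer_, nrow(pool)))
  for (pam in unique(pool$random_region)) {
    idx <- which(pool$random_region == pam)
    ref <- reporter_construct(design$upstream_homology, pam,
                              design$protospacer,
                              design$downstream_homology)
    cf <- classify_frame(pool$read[idx], ref)
    out$class[idx] <- cf$class
    out$delta[idx] <- cf$delta
  }
  out
}
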