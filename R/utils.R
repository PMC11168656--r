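#' @importFrom stats runif setNames aggregate
#' @importFrom utils read.delim write.table modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> allowed bases
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_dna <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[ACGT]*$", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Run `expr` under a fixed RNG state when seed is given, leaving the
# caller's RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single number in [0, 1] (got %s)", name,
          paste(format(x), collapse = ","))
  invisible(x)
}
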