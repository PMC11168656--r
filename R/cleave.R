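#' Gel lane intensities
#'
#' Integrated band intensities from one lane of an in vitro cleavage gel:
#' `a` is the undigested substrate band, `b` and `c` the two cleavage or
#' nicking products. Intensities are assumed background-subtracted; no
#' image analysis is performed here.
#'
#' @param a,b,c Non-negative intensities with a + b + c > 0.
#' @param label Optional lane label (e.g. PAM or temperature).
#' @return An object of class `gel_lanes`.
#' @export
gel_lanes <- function(a, b, c, label = NA_character_) {
  v <- c(a = a, b = b, c = c)
  if (any(!is.finite(v)) || any(v < 0))
    stopf("band intensities must be finite and non-negative")
  if (sum(v) <= 0) stopf("a + b + c must be positive")
  structure(list(a = a, b = b, c = c, label = as.character(label)),
            class = "gel_lanes")
}

#' Cleavage percentage from gel band intensities
#'
#' For a linear double-stranded substrate cut into two products, the
#' fraction of molecules with at least one cut is (b+c)/(a+b+c); assuming
#' the two cleavage events are independent with per-site probability f,
#' that fraction equals 1 - (1-f)^2, so
#' \deqn{cleavage(\%) = 100 (1 - \sqrt{1 - (b+c)/(a+b+c)})}
#'
#' @param lanes A [gel_lanes()] object, or the intensity `a` when `b` and
#'   `c` are given separately.
#' @param b,c Product band intensities (when `lanes` is the numeric `a`).
#' @return Cleavage percentage in \[0, 100\].
#' @examples
#' quantify_cleavage(gel_lanes(1, 1, 1))  # 100 * (1 - sqrt(1/3))
#' @export
quantify_cleavage <- function(lanes, b = NULL, c = NULL) {
  if (!inherits(lanes, "gel_lanes")) lanes <- gel_lanes(lanes, b, c)
  frac <- (lanes$b + lanes$c) / (lanes$a + lanes$b + lanes$c)
  100 * (1 - sqrt(1 - frac))
}

#' Summarise a panel of gel lanes
#'
#' @param lanes A list of [gel_lanes()] with distinct labels (a PAM panel
#'   or a temperature series).
#' @return Data.frame (label, a, b, c, cleavage_pct), one row per lane in
#'   input order.
#' @export
summarize_panel <- function(lanes) {
  if (length(lanes) == 0L) stopf("panel must contain at least one lane set")
  if (!all(vapply(lanes, inherits, logical(1), "gel_lanes")))
    stopf("panel entries must be gel_lanes objects")
  labs <- vapply(lanes, `[[`, character(1), "label")
  if (anyDuplicated(labs[!is.na(labs)]))
    stopf("duplicate lane labels: %s",
          paste(unique(labs[duplicated(labs)]), collapse = ", "))
  data.frame(label = labs,
             a = vapply(lanes, `[[`, numeric(1), "a"),
             b = vapply(lanes, `[[`, numeric(1), "b"),
             c = vapply(lanes, `[[`, numeric(1), "c"),
             cleavage_pct = vapply(lanes, quantify_cleavage, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Read a lane table (label, a, b, c) from TSV
#'
#' @param path TSV file with columns label, a, b, c.
#' @return List of [gel_lanes()].
#' @export
read_lanes_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "a", "b", "c")
  if (!all(need %in% names(d)))
    stopf("lane table needs columns: %s", paste(need, collapse = ", "))
  lapply(seq_len(nrow(d)), function(i)
    gel_lanes(d$a[i], d$b[i], d$c[i], d$label[i]))
}
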