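#' Position frequency matrix and information content of a PAM pool
#'
#' Converts 5-mer counts into a per-position base frequency matrix (PFM)
#' over PAM positions -5..-1 (-1 immediately 5' of the protospacer) and the
#' per-position information content used by sequence logos:
#' \deqn{IC(j) = 2 + \sum_b p_{bj} \log_2 p_{bj}} (0 log 0 = 0), so 2 bits
#' marks an invariant position and 0 bits a uniform one. The optional
#' small-sample correction subtracts e(n) = 3 / (2 ln(2) n), floored at 0.
#'
#' @param table A `pam_count_table` with `n_total > 0`.
#' @param correction Apply the small-sample correction (off by default,
#'   matching common logo-tool defaults).
#' @param baseline Optional `pam_count_table` of the unselected input
#'   library; when given, selected frequencies are divided by baseline
#'   frequencies position-wise and renormalised, removing library
#'   composition bias.
#' @return A `pam_profile`: `positions` (-5..-1), `pfm` (4 x 5, columns sum
#'   to 1), `ic` (bits), `n`, `small_sample_correction`.
#' @export
compute_profile <- function(table, correction = FALSE, baseline = NULL) {
  stopifnot(inherits(table, "pam_count_table"))
  if (table$n_total == 0L) stopf("empty PAM table: no reads to profile")
  pfm <- pfm_from_counts(table$counts)
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "pam_count_table"))
    if (baseline$n_total == 0L) stopf("empty baseline table")
    base_pfm <- pfm_from_counts(baseline$counts)
    if (any(base_pfm == 0 & pfm > 0))
      stopf("baseline frequency 0 where selected frequency > 0")
    ratio <- ifelse(base_pfm > 0, pfm / base_pfm, 0)
    pfm <- sweep(ratio, 2L, colSums(ratio), "/")
  }
  plogp <- ifelse(pfm > 0, pfm * log2(pfm), 0)
  ic <- 2 + colSums(plogp)
  if (correction) ic <- pmax(ic - 3 / (2 * log(2) * table$n_total), 0)
  structure(list(positions = -5:-1, pfm = pfm, ic = ic, n = table$n_total,
                 small_sample_correction = correction,
                 metadata = table$metadata),
            class = "pam_profile")
}

pfm_from_counts <- function(counts) {
  m <- matrix(0, 4, 5, dimnames = list(DNA_BASES, as.character(-5:-1)))
  if (length(counts)) {
    bases <- do.call(rbind, strsplit(names(counts), ""))
    for (j in seq_len(5L)) {
      agg <- tapply(as.numeric(counts), bases[, j], sum)
      m[names(agg), j] <- agg
    }
    m <- sweep(m, 2L, colSums(m), "/")
  }
  m
}

#' @export
print.pam_profile <- function(x, ...) {
  cat("PAM profile over positions -5..-1 (n =", x$n, "reads)\n")
  print(round(x$pfm, 3))
  cat("IC (bits):", paste(round(x$ic, 3), collapse = "  "), "\n")
  invisible(x)
}

#' Hierarchical PAM wheel from 5-mer counts
#'
#' A PAM wheel is a concentric-ring (Krona-style) chart: each ring is one
#' PAM position, read from the centre outward along `ring_order`, and each
#' wedge's angular span is proportional to the joint frequency of the base
#' path leading to it. Sibling wedges are ordered alphabetically and nest
#' exactly inside their parent's span.
#'
#' @param table A `pam_count_table` with `n_total > 0`.
#' @param ring_order PAM positions from the centre outward (default -1
#'   innermost, the base adjacent to the protospacer).
#' @return A `pam_wheel`: `ring_order` and `nodes`, a data.frame with
#'   `path`, `depth`, `base`, `count`, `fraction` (of parent) and
#'   `start_deg`/`end_deg`.
#' @export
compute_wheel <- function(table, ring_order = c(-1, -2, -3, -4, -5)) {
  stopifnot(inherits(table, "pam_count_table"))
  if (table$n_total == 0L) stopf("empty PAM table: no reads to chart")
  if (!setequal(ring_order, -5:-1) || length(ring_order) != 5L)
    stopf("ring_order must be a permutation of -5..-1")
  counts <- table$counts
  # char index of each ring position within the 5-mer (N1..N5 = -5..-1)
  char_idx <- 6L + ring_order
  kmers <- names(counts)
  paths <- vapply(kmers, function(k) {
    b <- strsplit(k, "")[[1]]
    paste(b[char_idx], collapse = "")
  }, character(1))

  nodes <- list()
  parent <- data.frame(path = "", count = as.numeric(table$n_total),
                       start_deg = 0, end_deg = 360,
                       stringsAsFactors = FALSE)
  for (depth in 1:5) {
    pref <- substr(paths, 1L, depth)
    agg <- tapply(as.numeric(counts), pref, sum)
    agg <- agg[order(names(agg))]          # alphabetical within parent
    parents <- substr(names(agg), 1L, depth - 1L)
    pidx <- match(parents, parent$path)
    rows <- data.frame(path = names(agg), depth = depth,
                       base = substr(names(agg), depth, depth),
                       count = as.numeric(agg),
                       fraction = as.numeric(agg) / parent$count[pidx],
                       start_deg = NA_real_, end_deg = NA_real_,
                       stringsAsFactors = FALSE)
    for (p in unique(pidx)) {
      sel <- which(pidx == p)
      span <- c(parent$start_deg[p], parent$end_deg[p])
      w <- rows$count[sel] / sum(rows$count[sel]) * (span[2] - span[1])
      ends <- span[1] + cumsum(w)
      rows$start_deg[sel] <- c(span[1], ends[-length(ends)])
      rows$end_deg[sel] <- ends
    }
    nodes[[depth]] <- rows
    parent <- rows
  }
  structure(list(ring_order = ring_order,
                 nodes = do.call(rbind, nodes),
                 n = table$n_total),
            class = "pam_wheel")
}

#' @export
print.pam_wheel <- function(x, ...) {
  cat("PAM wheel (rings centre-out:",
      paste(x$ring_order, collapse = ", "), ") with",
      nrow(x$nodes), "wedges, n =", x$n, "\n")
  invisible(x)
}

#' Export a PAM profile or wheel to JSON, TSV and SVG
#'
#' Writes `<stem>.json` (lossless machine-readable form), `<stem>.tsv`
#' (PFM/IC table or wedge table) and `<stem>.svg` (logo or wheel
#' rendering).
#'
#' @param x A `pam_profile` or `pam_wheel`.
#' @param stem Output path without extension.
#' @return Invisibly, the paths written.
#' @export
export_profile <- function(x, stem) UseMethod("export_profile")

#' @export
export_profile.pam_profile <- function(x, stem) {
  paths <- paste0(stem, c(".json", ".tsv", ".svg"))
  obj <- list(type = "pam_profile", positions = x$positions,
              pfm = as.data.frame(t(x$pfm)), ic = x$ic, n = x$n,
              small_sample_correction = x$small_sample_correction,
              metadata = x$metadata)
  jsonlite::write_json(obj, paths[1], auto_unbox = TRUE, digits = NA)
  tab <- data.frame(position = x$positions, t(x$pfm), ic = x$ic)
  write.table(tab, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(svg_logo(x), paths[3])
  invisible(paths)
}

#' @export
export_profile.pam_wheel <- function(x, stem) {
  paths <- paste0(stem, c(".json", ".tsv", ".svg"))
  obj <- list(type = "pam_wheel", ring_order = x$ring_order,
              nodes = x$nodes, n = x$n)
  jsonlite::write_json(obj, paths[1], auto_unbox = TRUE, digits = NA)
  write.table(x$nodes, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(svg_wheel(x), paths[3])
  invisible(paths)
}

#' Re-import an exported PAM profile
#'
#' @param path A `.json` file written by [export_profile()].
#' @return The reconstructed `pam_profile`.
#' @export
import_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "pam_profile"))
    stopf("not an exported pam_profile: %s", path)
  pfm <- t(as.matrix(obj$pfm))
  dimnames(pfm) <- list(DNA_BASES, as.character(-5:-1))
  structure(list(positions = as.integer(obj$positions), pfm = pfm,
                 ic = setNames(as.numeric(obj$ic), as.character(-5:-1)),
                 n = obj$n,
                 small_sample_correction = obj$small_sample_correction,
                 metadata = obj$metadata),
            class = "pam_profile")
}

BASE_COLORS <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")

# Hand-rolled SVG sequence logo: one column per PAM position, letters
# stacked by frequency * IC (bits).
svg_logo <- function(profile, width = 400, height = 220) {
  col_w <- width / 5
  plot_h <- height - 30
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    width, height))
  for (j in seq_len(5L)) {
    pos <- profile$positions[j]
    x0 <- (j - 1) * col_w
    lines <- c(lines, sprintf('<g class="logo-pos" id="pos%d">', pos))
    heights <- profile$pfm[, j] * profile$ic[j] / 2 * plot_h
    ord <- order(heights)    # tallest letter on top
    y <- plot_h
    for (b in DNA_BASES[ord]) {
      h <- heights[b]
      if (h > 0.1) {
        # a capital glyph at font-size 100 is ~72 units tall
        lines <- c(lines, sprintf(
          paste0('<text x="0" y="0" font-family="monospace" ',
                 'font-size="100" font-weight="bold" fill="%s" ',
                 'transform="translate(%.2f,%.2f) scale(%.4f,%.4f)">%s',
                 '</text>'),
          BASE_COLORS[b], x0 + 5, y, (col_w - 10) / 60, h / 72, b))
        y <- y - h
      }
    }
    lines <- c(lines, sprintf(
      '<text x="%.1f" y="%d" text-anchor="middle" font-size="14">%d</text>',
      x0 + col_w / 2, height - 8, pos), "</g>")
  }
  c(lines, "</svg>")
}

# Annular wedge path between angles a1 < a2 (degrees) and radii r1 < r2.
svg_wedge <- function(cx, cy, r1, r2, a1, a2, fill) {
  pt <- function(r, a) {
    th <- (a - 90) * pi / 180
    c(cx + r * cos(th), cy + r * sin(th))
  }
  large <- as.integer((a2 - a1) > 180)
  p1 <- pt(r1, a1); p2 <- pt(r2, a1); p3 <- pt(r2, a2); p4 <- pt(r1, a2)
  sprintf(paste0('<path d="M %.3f %.3f L %.3f %.3f ',
                 'A %.3f %.3f 0 %d 1 %.3f %.3f L %.3f %.3f ',
                 'A %.3f %.3f 0 %d 0 %.3f %.3f Z" ',
                 'fill="%s" stroke="white" stroke-width="0.5"/>'),
          p1[1], p1[2], p2[1], p2[2], r2, r2, large, p3[1], p3[2],
          p4[1], p4[2], r1, r1, large, p1[1], p1[2], fill)
}

svg_wheel <- function(wheel, size = 420) {
  cx <- size / 2; cy <- size / 2
  r_max <- size / 2 - 10
  r_step <- r_max / 6
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    size, size))
  for (depth in 1:5) {
    pos <- wheel$ring_order[depth]
    sub <- wheel$nodes[wheel$nodes$depth == depth, , drop = FALSE]
    lines <- c(lines, sprintf('<g class="wheel-ring" id="ring%d">', pos))
    for (i in seq_len(nrow(sub))) {
      span <- sub$end_deg[i] - sub$start_deg[i]
      if (span <= 0) next
      # full-circle wedges need two arcs; split at the midpoint
      a1 <- sub$start_deg[i]; a2 <- sub$end_deg[i]
      fill <- BASE_COLORS[sub$base[i]]
      r1 <- depth * r_step; r2 <- (depth + 1) * r_step
      if (span >= 360) {
        mid <- a1 + span / 2
        lines <- c(lines, svg_wedge(cx, cy, r1, r2, a1, mid, fill),
                   svg_wedge(cx, cy, r1, r2, mid, a2, fill))
      } else {
        lines <- c(lines, svg_wedge(cx, cy, r1, r2, a1, a2, fill))
      }
    }
    lines <- c(lines, "</g>")
  }
  c(lines, "</svg>")
}
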