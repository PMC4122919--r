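#' Per-site divergence score track
#'
#' Holds one real value per genome position: either a phyloP-like score
#' (positive = conserved), its negation (positive = divergent; the sign
#' convention used throughout the correlation analyses), or a
#' phastCons-like per-site conservation probability in \[0, 1\]. Positions a
#' track does not cover are `NA` (masked).
#'
#' @param values numeric vector, one entry per position; `NA` = missing.
#' @param kind one of `"phylop"`, `"negated_phylop"`,
#'   `"conservation_probability"`.
#' @return an object of class `score_track`.
#' @export
score_track <- function(values, kind = c("phylop", "negated_phylop",
                                         "conservation_probability")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind == "conservation_probability") {
    v <- values[!is.na(values)]
    if (any(v < 0 | v > 1))
      stop("conservation probabilities must lie in [0, 1]")
  }
  structure(list(values = values, kind = kind, length = length(values)),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat("score_track:", x$length, "bp, kind =", x$kind, "\n")
  cat("  covered:", sum(!is.na(x$values)), "sites; range",
      sprintf("[%.4g, %.4g]", min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Negate a phyloP-like track
#'
#' Flips the sign so that larger values mean more divergence. A `phylop`
#' track becomes `negated_phylop` and vice versa.
#' @param x a [score_track].
#' @return a [score_track].
#' @export
negate_track <- function(x) {
  stopifnot(inherits(x, "score_track"))
  if (x$kind == "conservation_probability")
    stop("cannot negate a probability track")
  score_track(-x$values,
              kind = if (x$kind == "phylop") "negated_phylop" else "phylop")
}

#' Read a per-site score track from fixedStep wiggle or bedGraph
#'
#' Parsing is delegated to `rtracklayer::import()`; the resulting ranges are
#' flattened to a per-site vector. Wiggle coordinates are 1-based, bedGraph
#' is 0-based half-open, both handled by the importer. Uncovered positions
#' are `NA`; overlapping bedGraph intervals are rejected.
#'
#' @param path file path.
#' @param format `"wig"` (fixedStep) or `"bedgraph"`.
#' @param kind see [score_track()].
#' @param genome_length genome size in bp.
#' @return a [score_track].
#' @export
read_score_track <- function(path, format = c("wig", "bedgraph"),
                             kind = c("phylop", "negated_phylop",
                                      "conservation_probability"),
                             genome_length) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path,
                            format = if (format == "wig") "wig" else "bedGraph")
  L <- as.integer(genome_length)
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  if (any(en > L)) stop("track extends beyond genome_length")
  cov <- integer(L)
  for (k in seq_along(st)) cov[st[k]:en[k]] <- cov[st[k]:en[k]] + 1L
  if (any(cov > 1L)) stop("overlapping intervals in score track")
  vals <- rep(NA_real_, L)
  sc <- GenomicRanges::mcols(gr)$score
  for (k in seq_along(st)) vals[st[k]:en[k]] <- sc[k]
  score_track(vals, kind)
}

#' Write a score track
#'
#' fixedStep wiggle (1-based, step 1) or bedGraph (0-based half-open, one
#' line per run of equal values). Missing positions break wiggle blocks and
#' are omitted from bedGraph.
#'
#' @param x a [score_track].
#' @param path output file.
#' @param format `"wig"` or `"bedgraph"`.
#' @param chrom chromosome name written in the file.
#' @export
write_score_track <- function(x, path, format = c("wig", "bedgraph"),
                              chrom = "chrM") {
  stopifnot(inherits(x, "score_track"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  ok <- !is.na(x$values)
  if (format == "wig") {
    i <- 1L
    while (i <= x$length) {
      if (!ok[i]) { i <- i + 1L; next }
      j <- i
      while (j < x$length && ok[j + 1L]) j <- j + 1L
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1", chrom, i), con)
      writeLines(sprintf("%.6g", x$values[i:j]), con)
      i <- j + 1L
    }
  } else {
    i <- 1L
    while (i <= x$length) {
      if (!ok[i]) { i <- i + 1L; next }
      j <- i
      while (j < x$length && ok[j + 1L] && x$values[j + 1L] == x$values[i]) j <- j + 1L
      writeLines(sprintf("%s\t%d\t%d\t%.6g", chrom, i - 1L, j, x$values[i]), con)
      i <- j + 1L
    }
  }
  invisible(path)
}
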