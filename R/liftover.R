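#' Alignment-based coordinate map between two reference dialects
#'
#' Builds a position-level map from one reference sequence to another
#' (e.g. between the classical mitochondrial coordinate system and a genome
#' assembly's copy of the same molecule) from a single global pairwise
#' alignment with affine gap costs, computed by
#' [Biostrings::pairwiseAlignment()]. A gap of length `k` costs
#' `gap_open + k * gap_extend` (both supplied as negative scores). The
#' ambiguity base `N` is scored as a mismatch against everything, including
#' itself, so placeholder bases never anchor the alignment.
#'
#' @param seq_source,seq_target character scalars or `DNAString`s over
#'   A/C/G/T/N.
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   negative). Defaults: +1 / -2 / -5 / -1.
#' @return an object of class `coordinate_map`: list with `map` (integer
#'   vector; entry `i` is the 0-based target position aligned to 0-based
#'   source position `i - 1`, or `NA` where the source base is deleted in
#'   the target), `source_length`, `target_length`, `score`.
#' @export
build_coordinate_map <- function(seq_source, seq_target, match = 1,
                                 mismatch = -2, gap_open = -5,
                                 gap_extend = -1) {
  s <- toupper(as.character(seq_source))
  t <- toupper(as.character(seq_target))
  if (!nzchar(s) || !nzchar(t)) stop("sequences must be non-empty")
  if (grepl("[^ACGTN]", s) || grepl("[^ACGTN]", t))
    stop("sequences must be over A/C/G/T/N")
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be supplied as non-positive scores")
  sub <- matrix(mismatch, 5, 5, dimnames = list(c(BASES, "N"), c(BASES, "N")))
  diag(sub)[1:4] <- match            # N-N stays a mismatch
  aln <- Biostrings::pairwiseAlignment(
    pattern = s, subject = t, type = "global",
    substitutionMatrix = sub,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  q <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(s))
  si <- 0L; ti <- 0L
  for (k in seq_along(p)) {
    sp <- p[k] != "-"; tp <- q[k] != "-"
    if (sp && tp) map[si + 1L] <- ti
    if (sp) si <- si + 1L
    if (tp) ti <- ti + 1L
  }
  structure(list(map = map, source_length = nchar(s), target_length = nchar(t),
                 score = Biostrings::score(aln)),
            class = "coordinate_map")
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat("coordinate_map:", x$source_length, "->", x$target_length, "bp;",
      sum(is.na(x$map)), "source position(s) unmapped; score", x$score, "\n")
  invisible(x)
}

#' Lift a single position through a coordinate map
#'
#' @param map a coordinate map from [build_coordinate_map()].
#' @param pos 0-based source position(s).
#' @return 0-based target position(s); `NA` where the source base has no
#'   aligned target base.
#' @export
lift_position <- function(map, pos) {
  stopifnot(inherits(map, "coordinate_map"))
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= map$source_length))
    stop("position out of range 0..", map$source_length - 1L)
  map$map[pos + 1L]
}
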