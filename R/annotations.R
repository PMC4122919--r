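GENE_CLASSES <- c("protein", "tRNA", "rRNA", "control", "other")

#' Gene annotation set
#'
#' Intervals with a name, strand and functional class over a circular
#' genome. Intervals are 0-based half-open internally (BED convention); an
#' interval crossing the origin is stored as two records sharing a name.
#'
#' @param name,start,end,strand,class parallel vectors; `strand` in `+`/`-`,
#'   `class` in `protein`, `tRNA`, `rRNA`, `control`, `other`.
#' @param genome_length genome size in bp.
#' @param circular logical flag.
#' @param description optional parallel character vector.
#' @return an object of class `annotation_set`: a data.frame with attributes
#'   `genome_length` and `circular`.
#' @export
annotation_set <- function(name, start, end, strand, class, genome_length,
                           circular = TRUE, description = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end > genome_length) || any(start >= end))
    stop("annotation intervals must satisfy 0 <= start < end <= genome_length")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(class %in% GENE_CLASSES))
    stop("unknown class token: ", paste(setdiff(class, GENE_CLASSES), collapse = ", "))
  df <- data.frame(name = as.character(name), start = start, end = end,
                   strand = as.character(strand), class = as.character(class),
                   stringsAsFactors = FALSE)
  if (!is.null(description)) df$description <- as.character(description)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, genome_length = as.integer(genome_length),
            circular = isTRUE(circular),
            class = c("annotation_set", "data.frame"))
}

#' Read gene annotations from a BED6-like file
#'
#' Column 4 carries `name|class` (class after a `|` separator, drawn from
#' `protein`/`tRNA`/`rRNA`/`control`/`other`); column 6 the strand.
#' Coordinates on disk are 0-based half-open.
#'
#' @param path file path.
#' @param genome_length genome size in bp.
#' @param circular logical flag.
#' @return an [annotation_set].
#' @export
read_annotations <- function(path, genome_length, circular = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(annotation_set(character(), integer(), integer(), character(),
                          character(), genome_length, circular))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6L)) stop("annotation BED needs 6 columns")
  nm <- vapply(f, `[[`, "", 4L)
  parts <- strsplit(nm, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("annotation name column must be 'name|class'")
  cls <- vapply(parts, `[[`, "", 2L)
  bad <- setdiff(unique(cls), GENE_CLASSES)
  if (length(bad)) stop("unknown class token: ", paste(bad, collapse = ", "))
  annotation_set(name = vapply(parts, `[[`, "", 1L),
                 start = as.integer(vapply(f, `[[`, "", 2L)),
                 end = as.integer(vapply(f, `[[`, "", 3L)),
                 strand = vapply(f, `[[`, "", 6L),
                 class = cls,
                 genome_length = genome_length, circular = circular)
}

#' @rdname read_annotations
#' @param x an [annotation_set].
#' @param chrom chromosome name to write.
#' @export
write_annotations <- function(x, path, chrom = "chrM") {
  stopifnot(inherits(x, "annotation_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6: chrom start end name|class score strand", con)
  if (nrow(x))
    writeLines(sprintf("%s\t%d\t%d\t%s|%s\t0\t%s", chrom, x$start, x$end,
                       x$name, x$class, x$strand), con)
  invisible(path)
}

#' Called-element set
#'
#' Non-overlapping, sorted, half-open intervals on a genome: the output of
#' element calling (polymorphism-HMM or divergence-based) or the truth set
#' of a simulation.
#'
#' @param start,end integer vectors of 0-based half-open bounds.
#' @param genome_length genome size in bp.
#' @param label per-element labels (recycled).
#' @param source free-text provenance tag (e.g. `"popcons_hmm"`).
#' @return an object of class `element_set`.
#' @export
element_set <- function(start, end, genome_length, label = "element",
                        source = "unknown") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end > genome_length) || any(start >= end))
    stop("element intervals must satisfy 0 <= start < end <= genome_length")
  o <- order(start)
  start <- start[o]; end <- end[o]
  label <- rep_len(as.character(label), length(start))[o]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
    stop("elements within a set must not overlap")
  df <- data.frame(start = start, end = end, label = label,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, genome_length = as.integer(genome_length), source = source,
            class = c("element_set", "data.frame"))
}

#' @export
print.element_set <- function(x, ...) {
  w <- x$end - x$start
  cat("element_set (", attr(x, "source"), "): ", nrow(x), " elements, ",
      sum(w), " bp total",
      if (nrow(x)) sprintf(", mean length %.1f bp", mean(w)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Read/write element calls as BED3+label
#'
#' @param path file path.
#' @param genome_length genome size in bp.
#' @param source provenance tag stored on the result.
#' @return an [element_set].
#' @export
read_elements <- function(path, genome_length, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(element_set(integer(), integer(), genome_length, source = source))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("element BED needs at least 3 columns")
  element_set(start = as.integer(vapply(f, `[[`, "", 2L)),
              end = as.integer(vapply(f, `[[`, "", 3L)),
              label = vapply(f, function(v) if (length(v) >= 4L) v[[4L]] else "element", ""),
              genome_length = genome_length, source = source)
}

#' @rdname read_elements
#' @param x an [element_set]. Intervals are written sorted; abutting
#'   intervals with the same label are merged.
#' @param chrom chromosome name to write.
#' @export
write_elements <- function(x, path, chrom = "chrM") {
  stopifnot(inherits(x, "element_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED3+label: chrom start end label", con)
  if (nrow(x)) {
    # merge abutting same-label runs
    keep <- rep(TRUE, nrow(x))
    st <- x$start; en <- x$end; lb <- x$label
    j <- 1L
    for (i in seq_len(nrow(x))[-1L]) {
      if (st[i] == en[j] && lb[i] == lb[j]) { en[j] <- en[i]; keep[i] <- FALSE }
      else j <- i
    }
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, st[keep], en[keep], lb[keep]), con)
  }
  invisible(path)
}

# IRanges view of an element set (internal)
as_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)
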