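P_FLOOR <- 2.2e-16

#' Spearman rank correlation with midranks and t-approximation p-value
#'
#' Both vectors are transformed to average (mid-) ranks and their Pearson
#' correlation taken; ties are therefore handled exactly as allele-count
#' data require (only four distinct values, so ties dominate). The p-value
#' uses the t approximation with n - 2 degrees of freedom, which is
#' accurate at genomic n; printed reports floor it at 2.2e-16, the raw
#' value is retained in the result.
#'
#' Pairs with a missing value in either vector are dropped.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs for a
#'   defined p-value).
#' @return an object of class `correlation_result`: list with `rho`,
#'   `p_value`, `n`, `method`, `ties`. `rho` is `NA` with a warning when
#'   either vector has zero variance.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  res <- structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                        method = "spearman_midrank", ties = NA),
                   class = "correlation_result")
  if (n < 3L) { warning("fewer than 3 complete pairs"); return(res) }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined")
    return(res)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  res$ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  res$rho <- rho
  if (abs(rho) >= 1) {
    res$p_value <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    res$p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  res
}

format_p <- function(p) {
  if (is.na(p)) "NA" else if (p < P_FLOOR) "< 2.2e-16" else sprintf("%.4g", p)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Spearman's rho =", if (is.na(x$rho)) "NA" else sprintf("%.4f", x$rho),
      "; P", if (!is.na(x$p_value) && x$p_value < P_FLOOR) "" else "=",
      format_p(x$p_value), "; n =", x$n,
      if (isTRUE(x$ties)) "(midranks, ties present)" else "", "\n")
  invisible(x)
}

#' Window averages of a per-site track
#'
#' Arithmetic mean per window; `NA` (masked) sites are excluded from each
#' window's mean. `step = width` gives adjacent windows (the 10-bp windows
#' of the site-level analyses); `step = 1` gives sliding windows. In linear
#' mode a trailing partial window is kept when it spans at least half a
#' window; in circular mode windows wrap around the origin and every start
#' position on the step grid yields a full-width window.
#'
#' @param values numeric per-site vector (NA = masked).
#' @param width window width in bp (>= 1).
#' @param step distance between window starts (default `width`).
#' @param circular wrap windows around the end of the sequence.
#' @return numeric vector of window means (`NaN` where a window contains
#'   only masked sites).
#' @export
window_average <- function(values, width, step = width, circular = FALSE) {
  L <- length(values)
  width <- as.integer(width); step <- as.integer(step)
  if (width < 1L || step < 1L) stop("width and step must be >= 1")
  if (width > L) stop("width exceeds sequence length")
  if (circular) {
    starts <- seq(1L, L, by = step)
    vapply(starts, function(s) {
      idx <- ((s - 1L + 0:(width - 1L)) %% L) + 1L
      mean(values[idx], na.rm = TRUE)
    }, numeric(1))
  } else {
    starts <- seq(1L, max(L - width + 1L, 1L), by = step)
    out <- vapply(starts, function(s) mean(values[s:(s + width - 1L)], na.rm = TRUE),
                  numeric(1))
    tail_start <- starts[length(starts)] + step
    if (tail_start <= L && (L - tail_start + 1L) >= width / 2) {
      out <- c(out, mean(values[tail_start:L], na.rm = TRUE))
    }
    out
  }
}

#' Per-gene polymorphism-divergence correlations
#'
#' For each annotated gene, the Spearman correlation between the per-site
#' distinct-allele count and the negated conservation score across the gene
#' span, and — when GLM residuals are supplied — the same correlation with
#' the replication-bias-corrected polymorphism residuals in place of raw
#' counts. Genes spanning fewer than 3 usable sites get `NA` correlations.
#'
#' @param sites a [site_table].
#' @param scores numeric per-site vector of negated conservation scores
#'   (larger = more divergent) or a [score_track] of kind `negated_phylop`.
#' @param annotations an [annotation_set]; rows of class `other` are
#'   skipped.
#' @param residuals optional per-site numeric vector of corrected
#'   polymorphism (e.g. `residuals(fit)` mapped back to genome positions,
#'   `NA` where the fit excluded sites).
#' @param alpha significance threshold for the reported tally.
#' @return a data.frame with one row per gene (name, description, start,
#'   end, rho, p, rho_corrected, p_corrected) and attributes
#'   `n_significant`, `n_significant_corrected`, `n_genes`, `alpha`.
#' @export
per_gene_correlations <- function(sites, scores, annotations, residuals = NULL,
                                  alpha = 0.05) {
  stopifnot(inherits(sites, "site_table"), inherits(annotations, "annotation_set"))
  if (inherits(scores, "score_track")) scores <- scores$values
  if (length(scores) != sites$length) stop("scores length mismatch")
  genes <- annotations[annotations$class != "other", , drop = FALSE]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    idx <- (genes$start[i] + 1L):genes$end[i]
    raw <- suppressWarnings(spearman_cor(sites$allele_count[idx], scores[idx]))
    corr <- if (!is.null(residuals))
      suppressWarnings(spearman_cor(residuals[idx], scores[idx]))
    else list(rho = NA_real_, p_value = NA_real_)
    data.frame(name = genes$name[i],
               description = if ("description" %in% names(genes))
                 genes$description[i] else genes$class[i],
               start = genes$start[i], end = genes$end[i],
               rho = raw$rho, p = raw$p_value,
               rho_corrected = corr$rho, p_corrected = corr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(name = character(), description = character(),
                                      start = integer(), end = integer(),
                                      rho = numeric(), p = numeric(),
                                      rho_corrected = numeric(), p_corrected = numeric())
  # BH-adjusted column as a clearly-marked extension beyond the raw-p table
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  attr(out, "n_genes") <- nrow(out)
  attr(out, "n_significant") <- sum(out$p < alpha, na.rm = TRUE)
  attr(out, "n_significant_corrected") <- sum(out$p_corrected < alpha, na.rm = TRUE)
  attr(out, "alpha") <- alpha
  out
}

SITE_CLASSES <- c("second_codon_position", "fourfold_degenerate", "other_coding",
                  "noncoding_control", "noncoding_other", "rna_gene")

#' Classify genome sites by codon position and annotation class
#'
#' Protein-coding genes are read codon by codon 5'->3' on the coding strand
#' (minus-strand genes are reverse-complemented). The middle base of every
#' codon is `second_codon_position` (virtually always nonsynonymous); the
#' third base is `fourfold_degenerate` when the codon's first two bases
#' make all four third-base completions encode the same amino acid under
#' the vertebrate mitochondrial genetic code (translation table 2), and
#' `other_coding` otherwise (as are first positions). Gene spans whose
#' length is not a multiple of 3 have the trailing partial codon skipped
#' with a warning. RNA genes are `rna_gene`, control-region sites
#' `noncoding_control`, everything unannotated `noncoding_other`.
#'
#' Sites already labelled by an earlier annotation record keep their label
#' when a later protein record overlaps them (precedence by annotation
#' order, with a warning).
#'
#' @param annotations an [annotation_set].
#' @param reference_sequence character scalar or `DNAString`, length equal
#'   to the genome.
#' @return character vector of per-site labels (one of
#'   `second_codon_position`, `fourfold_degenerate`, `other_coding`,
#'   `noncoding_control`, `noncoding_other`, `rna_gene`).
#' @export
classify_sites <- function(annotations, reference_sequence) {
  stopifnot(inherits(annotations, "annotation_set"))
  L <- attr(annotations, "genome_length")
  seq <- toupper(as.character(reference_sequence))
  if (nchar(seq) != L) stop("reference sequence length must equal genome length")
  bases <- strsplit(seq, "")[[1]]
  code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  prefixes <- unique(substr(names(code), 1, 2))
  fourfold_prefix <- vapply(prefixes, function(p) {
    aa <- code[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1L
  }, logical(1))
  names(fourfold_prefix) <- prefixes

  lab <- rep("noncoding_other", L)
  ctrl <- annotations[annotations$class == "control", , drop = FALSE]
  for (i in seq_len(nrow(ctrl)))
    lab[(ctrl$start[i] + 1L):ctrl$end[i]] <- "noncoding_control"
  rna <- annotations[annotations$class %in% c("tRNA", "rRNA"), , drop = FALSE]
  for (i in seq_len(nrow(rna)))
    lab[(rna$start[i] + 1L):rna$end[i]] <- "rna_gene"

  prot <- annotations[annotations$class == "protein", , drop = FALSE]
  coding_labels <- c("second_codon_position", "fourfold_degenerate", "other_coding")
  n_partial <- 0L
  for (i in seq_len(nrow(prot))) {
    span <- (prot$start[i] + 1L):prot$end[i]
    if (any(lab[span] %in% coding_labels)) {
      warning("protein gene ", prot$name[i],
              " overlaps an earlier coding annotation; earlier record takes precedence")
      span <- span[!(lab[span] %in% coding_labels)]
      if (!length(span)) next
    }
    len <- length(span)
    usable <- len - len %% 3L
    if (len %% 3L) n_partial <- n_partial + 1L
    if (!usable) next
    if (prot$strand[i] == "+") {
      cod_span <- span[seq_len(usable)]
      ord <- cod_span
    } else {
      cod_span <- span[(len - usable + 1L):len]
      ord <- rev(cod_span)                       # 5'->3' on the coding strand
    }
    b <- bases[ord]
    if (prot$strand[i] == "-")
      b <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
    pos_in_codon <- rep(1:3, length.out = usable)
    l <- rep("other_coding", usable)
    l[pos_in_codon == 2L] <- "second_codon_position"
    third <- which(pos_in_codon == 3L)
    pref <- paste0(b[third - 2L], b[third - 1L])
    ff <- !is.na(fourfold_prefix[pref]) & fourfold_prefix[pref]
    l[third[ff]] <- "fourfold_degenerate"
    lab[ord] <- l
  }
  if (n_partial)
    warning(n_partial, " protein gene(s) with length not divisible by 3; ",
            "trailing partial codon(s) skipped")
  lab
}

#' Minor-allele-frequency vs divergence correlation
#'
#' Spearman correlation between the minor allele frequency of biallelic
#' sites and the negated conservation score at those sites, a second,
#' frequency-based signature of purifying selection (deleterious alleles
#' are held at lower frequencies at conserved sites).
#'
#' @param sites a [site_table] with `maf` present.
#' @param scores numeric per-site vector of negated conservation scores or
#'   a [score_track].
#' @return a correlation result (see [spearman_cor()]); `rho = NA` when fewer than 3 biallelic
#'   sites qualify or the MAFs are constant.
#' @export
maf_divergence_correlation <- function(sites, scores) {
  stopifnot(inherits(sites, "site_table"))
  if (inherits(scores, "score_track")) scores <- scores$values
  if (length(scores) != sites$length) stop("scores length mismatch")
  if (is.null(sites$maf)) stop("site table carries no minor allele frequencies")
  use <- sites$allele_count == 2L & !is.na(sites$maf)
  if (sum(use) < 3L) {
    warning("fewer than 3 biallelic sites with MAF")
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = sum(use),
                          method = "spearman_midrank", ties = NA),
                     class = "correlation_result"))
  }
  spearman_cor(sites$maf[use], scores[use])
}
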