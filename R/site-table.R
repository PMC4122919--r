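#' Per-site polymorphism table
#'
#' A `site_table` holds, for every position of a (typically circular) genome,
#' the number of distinct nucleotide alleles observed in a population sample
#' (1 = monomorphic, up to 4), and optionally the per-allele chromosome counts
#' from which minor allele frequencies and downsampled tables can be derived.
#'
#' Positions are 0-based internally: element `i` of the per-site vectors
#' describes genome position `i - 1`. Input SNP files use 1-based positions
#' and are converted at the boundary.
#'
#' @param allele_count integer vector, one entry per genome position, values
#'   in 1..4.
#' @param circular logical; is the genome circular?
#' @param sample_counts optional integer matrix with one row per position and
#'   columns `A`, `C`, `G`, `T` giving the number of sampled chromosomes
#'   carrying each allele. Row sums are the per-site sample sizes.
#' @param maf optional numeric vector of minor allele frequencies in
#'   (0, 0.5] for biallelic sites, `NA` elsewhere.
#'
#' @return An object of class `site_table`.
#' @export
site_table <- function(allele_count, circular = TRUE, sample_counts = NULL,
                       maf = NULL) {
  allele_count <- as.integer(allele_count)
  if (any(is.na(allele_count)) || any(allele_count < 1L) || any(allele_count > 4L))
    stop("allele_count entries must be integers in 1..4")
  L <- length(allele_count)
  if (!is.null(sample_counts)) {
    sample_counts <- as.matrix(sample_counts)
    if (nrow(sample_counts) != L || ncol(sample_counts) != 4L)
      stop("sample_counts must be an L x 4 matrix (columns A, C, G, T)")
    storage.mode(sample_counts) <- "integer"
    colnames(sample_counts) <- c("A", "C", "G", "T")
    if (any(sample_counts < 0L)) stop("sample_counts must be non-negative")
    if (any(rowSums(sample_counts) < 1L))
      stop("each site needs at least one sampled chromosome")
    obs <- rowSums(sample_counts > 0L)
    if (any(obs != allele_count))
      stop("allele_count inconsistent with sample_counts at site(s) ",
           paste(utils::head(which(obs != allele_count) - 1L, 5L), collapse = ", "),
           " (0-based)")
  }
  if (!is.null(maf)) {
    maf <- as.numeric(maf)
    if (length(maf) != L) stop("maf must have one entry per position")
    bad <- !is.na(maf) & (maf <= 0 | maf > 0.5)
    if (any(bad)) stop("maf values must lie in (0, 0.5]")
  }
  structure(list(allele_count = allele_count,
                 sample_counts = sample_counts,
                 maf = maf,
                 length = L,
                 circular = isTRUE(circular)),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat("site_table:", x$length, "bp",
      if (x$circular) "(circular)" else "(linear)", "\n")
  tab <- tabulate(x$allele_count, 4L)
  cat("  distinct-allele counts 1:4 =", paste(tab, collapse = " / "), "\n")
  cat("  polymorphic sites:", sum(x$allele_count > 1L),
      sprintf("(%.1f%%)", 100 * mean(x$allele_count > 1L)), "\n")
  if (!is.null(x$sample_counts))
    cat("  sample sizes: ", min(rowSums(x$sample_counts)), "-",
        max(rowSums(x$sample_counts)), " chromosomes/site\n", sep = "")
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

#' Read a tab-separated SNP table into a site_table
#'
#' Two dialects are supported. `positions_with_alleles` has columns
#' `position`, `ref`, `alt` (1-based positions, one row per alternate
#' allele; several rows may share a position). `positions_with_counts` has
#' columns `position`, `allele`, `count` with one row per observed allele
#' (reference included) and its chromosome count. Lines starting with `#`
#' are comments; a `# n_samples=<int>` header (or the `n_samples` argument)
#' gives the sample size used to fill unlisted, monomorphic positions in the
#' counts dialect.
#'
#' Positions absent from the file are monomorphic (`allele_count = 1`).
#' Insertion/deletion rows (allele symbols longer than one base or `-`) are
#' skipped with a warning; only single-nucleotide variants are analyzed.
#'
#' @param path file path.
#' @param dialect `"positions_with_alleles"` or `"positions_with_counts"`.
#' @param genome_length genome size in bp.
#' @param n_samples sample size for monomorphic fill in the counts dialect
#'   (overridden by a `# n_samples=` header in the file).
#' @param reference optional reference sequence (character scalar) giving the
#'   allele carried by monomorphic fill positions; defaults to `"A"` at every
#'   fill site (the identity is immaterial to all analyses, only counts are).
#' @param circular logical flag stored on the result.
#' @return a [site_table].
#' @export
read_snp_table <- function(path, dialect = c("positions_with_alleles",
                                             "positions_with_counts"),
                           genome_length, n_samples = NULL, reference = NULL,
                           circular = TRUE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("n_samples=\\d+", hdr))
  if (length(m)) n_samples <- as.integer(sub("n_samples=", "", m[[1]]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  L <- as.integer(genome_length)

  ref_base <- rep("A", L)
  if (!is.null(reference)) {
    reference <- toupper(as.character(reference))
    if (nchar(reference) != L) stop("reference length must equal genome_length")
    ref_base <- strsplit(reference, "")[[1]]
  }

  if (!length(lines)) {
    if (dialect == "positions_with_counts") {
      if (is.null(n_samples)) stop("counts dialect needs n_samples for monomorphic fill")
      cnt <- matrix(0L, L, 4, dimnames = list(NULL, BASES))
      cnt[cbind(seq_len(L), match(ref_base, BASES))] <- as.integer(n_samples)
      return(site_table(rep(1L, L), circular, sample_counts = cnt,
                        maf = rep(NA_real_, L)))
    }
    return(site_table(rep(1L, L), circular))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_needed <- 3L
  bad <- which(lengths(fields) < ncol_needed)
  if (length(bad)) stop("line ", bad[1], ": expected at least 3 tab-separated fields")
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  if (any(is.na(pos1)))
    stop("line ", which(is.na(pos1))[1], ": non-integer position")
  out <- which(pos1 < 1L | pos1 > L)
  if (length(out))
    stop("line ", out[1], ": position ", pos1[out[1]], " outside 1..", L)

  if (dialect == "positions_with_alleles") {
    ref <- toupper(vapply(fields, `[[`, "", 2L))
    alt <- toupper(vapply(fields, `[[`, "", 3L))
    indel <- nchar(ref) != 1L | nchar(alt) != 1L | ref == "-" | alt == "-"
    if (any(indel)) {
      warning(sum(indel), " insertion/deletion record(s) skipped; only SNPs are used")
      ref <- ref[!indel]; alt <- alt[!indel]; pos1 <- pos1[!indel]
    }
    bad_sym <- which(!(ref %in% BASES) | !(alt %in% BASES))
    if (length(bad_sym))
      stop("line ", bad_sym[1], ": allele symbol outside A/C/G/T")
    # distinct alleles per site = union of ref and alts seen there
    seen <- matrix(FALSE, L, 4, dimnames = list(NULL, BASES))
    seen[cbind(pos1, match(ref, BASES))] <- TRUE
    seen[cbind(pos1, match(alt, BASES))] <- TRUE
    ac <- rep(1L, L)
    listed <- unique(pos1)
    ac[listed] <- pmin(rowSums(seen[listed, , drop = FALSE]), 4L)
    return(site_table(ac, circular))
  }

  # positions_with_counts
  allele <- toupper(vapply(fields, `[[`, "", 2L))
  count <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  indel <- nchar(allele) != 1L | allele == "-"
  if (any(indel)) {
    warning(sum(indel), " insertion/deletion record(s) skipped; only SNPs are used")
    allele <- allele[!indel]; count <- count[!indel]; pos1 <- pos1[!indel]
  }
  bad_sym <- which(!(allele %in% BASES))
  if (length(bad_sym)) stop("line ", bad_sym[1], ": allele symbol outside A/C/G/T")
  if (any(is.na(count) | count < 0L)) stop("counts must be non-negative integers")
  cnt <- matrix(0L, L, 4, dimnames = list(NULL, BASES))
  idx <- cbind(pos1, match(allele, BASES))
  # accumulate (duplicate rows for the same allele add up)
  for (k in seq_along(pos1)) cnt[idx[k, 1], idx[k, 2]] <- cnt[idx[k, 1], idx[k, 2]] + count[k]
  listed <- unique(pos1)
  unlisted <- setdiff(seq_len(L), listed)
  if (length(unlisted)) {
    if (is.null(n_samples)) stop("counts dialect needs n_samples for monomorphic fill")
    cnt[cbind(unlisted, match(ref_base[unlisted], BASES))] <- as.integer(n_samples)
  }
  ac <- pmin(rowSums(cnt > 0L), 4L)
  maf <- rep(NA_real_, L)
  bi <- which(ac == 2L)
  if (length(bi)) {
    n_i <- rowSums(cnt[bi, , drop = FALSE])
    mn <- apply(cnt[bi, , drop = FALSE], 1, function(v) min(v[v > 0L]))
    maf[bi] <- mn / n_i
  }
  site_table(as.integer(ac), circular, sample_counts = cnt, maf = maf)
}

#' Write a site_table as a tab-separated SNP table
#'
#' Inverse of [read_snp_table()]. The alleles dialect writes one row per
#' non-reference allele at polymorphic sites (the alphabetically first
#' observed allele plays the reference role when none is known); the counts
#' dialect writes one row per observed allele at polymorphic sites plus a
#' `# n_samples=` header used for monomorphic fill on re-reading.
#'
#' @param x a [site_table]; the counts dialect requires `sample_counts`.
#' @param path output file.
#' @param dialect see [read_snp_table()].
#' @export
write_snp_table <- function(x, path, dialect = c("positions_with_alleles",
                                                 "positions_with_counts")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "positions_with_counts") {
    if (is.null(x$sample_counts)) stop("counts dialect requires sample_counts")
    n <- rowSums(x$sample_counts)
    if (length(unique(n)) != 1L)
      stop("counts dialect writer requires a uniform sample size")
    writeLines(c("# mitopopcons SNP table (positions_with_counts)",
                 paste0("# n_samples=", n[1]),
                 "# position\tallele\tcount"), con)
    poly <- which(x$allele_count > 1L)
    for (i in poly) {
      v <- x$sample_counts[i, ]
      for (b in BASES[v > 0L])
        writeLines(paste(i, b, v[b], sep = "\t"), con)
    }
  } else {
    writeLines(c("# mitopopcons SNP table (positions_with_alleles)",
                 "# position\tref\talt"), con)
    poly <- which(x$allele_count > 1L)
    for (i in poly) {
      if (!is.null(x$sample_counts)) {
        pres <- BASES[x$sample_counts[i, ] > 0L]
      } else {
        pres <- BASES[seq_len(x$allele_count[i])]  # allele identities unknown
      }
      for (b in pres[-1L]) writeLines(paste(i, pres[1L], b, sep = "\t"), con)
    }
  }
  invisible(path)
}
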