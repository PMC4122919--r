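#' Base pairs shared by two element sets
#'
#' Total length of the intersection of the two interval unions, via
#' IRanges arithmetic.
#'
#' @param a,b [element_set]s over the same genome length.
#' @return integer bp.
#' @export
overlap_bp <- function(a, b) {
  stopifnot(inherits(a, "element_set"), inherits(b, "element_set"))
  if (attr(a, "genome_length") != attr(b, "genome_length"))
    stop("element sets are on genomes of different lengths")
  if (!nrow(a) || !nrow(b)) return(0L)
  ia <- IRanges::reduce(as_iranges(a))
  ib <- IRanges::reduce(as_iranges(b))
  sum(IRanges::width(IRanges::intersect(ia, ib)))
}

#' Permutation test for overlap between two element sets
#'
#' The observed statistic is the number of base pairs constrained
#' according to both sets ([overlap_bp()]). Null overlaps are obtained by
#' permuting the coordinates of `a` on the circular genome while `b` stays
#' fixed: under the default `independent_uniform_circular` scheme every
#' element of `a` is placed at an independent uniform start with its
#' length preserved (placed elements may overlap; the union is what
#' counts), and under `rotation` a single uniform circular offset shifts
#' all of `a`, preserving spacing. The empirical p-value uses the +1
#' correction, `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`, so it is
#' never exactly zero and is reported as below `1/(n_perm + 1)` when no
#' permutation reaches the observed overlap.
#'
#' @param a,b [element_set]s on the same (circular) genome.
#' @param n_perm number of permutations (default 10,000).
#' @param scheme `"independent_uniform_circular"` or `"rotation"`.
#' @param seed integer seed.
#' @return an object of class `overlap_test`: `observed`, `perm`
#'   (numeric vector of permuted overlaps), `p_value`, `n_perm`, `scheme`,
#'   `seed`.
#' @export
permutation_overlap_test <- function(a, b, n_perm = 10000L,
                                     scheme = c("independent_uniform_circular",
                                                "rotation"),
                                     seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(a, "element_set"), inherits(b, "element_set"))
  L <- attr(a, "genome_length")
  if (L != attr(b, "genome_length"))
    stop("element sets are on genomes of different lengths")
  if (!is.null(seed)) set.seed(seed)
  out <- structure(list(observed = overlap_bp(a, b), perm = numeric(0),
                        p_value = 1, n_perm = as.integer(n_perm),
                        scheme = scheme, seed = seed),
                   class = "overlap_test")
  if (!nrow(a)) {
    warning("empty element set 'a': p = 1")
    return(out)
  }
  bcov <- logical(L)
  for (i in seq_len(nrow(b))) bcov[(b$start[i] + 1L):b$end[i]] <- TRUE
  lens <- a$end - a$start
  offs <- lapply(lens, function(l) 0:(l - 1L))
  perm <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    if (scheme == "rotation") {
      starts <- (a$start + sample.int(L, 1L) - 1L) %% L
    } else {
      starts <- sample.int(L, length(lens), replace = TRUE) - 1L
    }
    idx <- unlist(mapply(function(s, o) (s + o) %% L, starts, offs,
                         SIMPLIFY = FALSE), use.names = FALSE)
    perm[p] <- sum(bcov[unique(idx) + 1L])
  }
  out$perm <- perm
  out$p_value <- (1 + sum(perm >= out$observed)) / (1 + n_perm)
  out
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Permutation overlap test (", x$scheme, ", ", x$n_perm,
      " permutations)\n", sep = "")
  cat("  observed overlap:", x$observed, "bp; null mean",
      sprintf("%.1f", mean(x$perm)), "bp\n")
  if (length(x$perm) && !any(x$perm >= x$observed))
    cat("  P <", format(1 / (1 + x$n_perm), digits = 3), "\n")
  else cat("  P =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Summarize called elements against gene annotations
#'
#' @param elements an [element_set].
#' @param annotations an [annotation_set]; genic bp are the union of all
#'   annotated gene spans (`protein`, `tRNA`, `rRNA`), with the control
#'   region counted as genic when `control_as_genic = TRUE`.
#' @param control_as_genic logical (default `FALSE`).
#' @return list: `n_elements`, `mean_length`, `total_bp`,
#'   `frac_intergenic_bp` (fraction of element bp outside genic bp) and
#'   `frac_genic_recovered` (fraction of genic bp inside elements).
#' @export
summarize_elements <- function(elements, annotations, control_as_genic = FALSE) {
  stopifnot(inherits(elements, "element_set"), inherits(annotations, "annotation_set"))
  L <- attr(elements, "genome_length")
  classes <- c("protein", "tRNA", "rRNA", if (control_as_genic) "control")
  g <- annotations[annotations$class %in% classes, , drop = FALSE]
  gcov <- logical(L)
  for (i in seq_len(nrow(g))) gcov[(g$start[i] + 1L):g$end[i]] <- TRUE
  ecov <- logical(L)
  for (i in seq_len(nrow(elements)))
    ecov[(elements$start[i] + 1L):elements$end[i]] <- TRUE
  w <- elements$end - elements$start
  list(n_elements = nrow(elements),
       mean_length = if (length(w)) mean(w) else NA_real_,
       total_bp = sum(w),
       frac_intergenic_bp = if (sum(ecov)) sum(ecov & !gcov) / sum(ecov) else NA_real_,
       frac_genic_recovered = if (sum(gcov)) sum(ecov & gcov) / sum(gcov) else 0)
}

#' Downsample allele sample counts without replacement
#'
#' At each site, draws `n` chromosomes from the full per-allele counts
#' (a multivariate hypergeometric draw) and recounts the number of
#' distinct alleles observed — the rarefaction step of the sample-size
#' power analysis.
#'
#' @param sites a [site_table] with `sample_counts` (tables without
#'   per-allele counts cannot be downsampled and are refused).
#' @param n chromosomes to draw; must not exceed any site's sample size.
#' @param seed optional integer seed.
#' @return a [site_table] with the downsampled counts, allele counts and
#'   minor allele frequencies.
#' @export
downsample_alleles <- function(sites, n, seed = NULL) {
  stopifnot(inherits(sites, "site_table"))
  if (is.null(sites$sample_counts))
    stop("site table has no per-allele sample counts; downsampling requires them")
  n <- as.integer(n)
  tot <- rowSums(sites$sample_counts)
  if (any(n > tot)) {
    bad <- which(n > tot)[1] - 1L
    stop("n = ", n, " exceeds the sample size ", tot[bad + 1L],
         " at site ", bad, " (0-based)")
  }
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- sites$length
  draws <- matrix(0L, L, 4L, dimnames = list(NULL, BASES))
  remaining_pool <- tot
  remaining_draw <- rep(n, L)
  for (j in 1:4) {
    cnt <- sites$sample_counts[, j]
    if (j < 4L) {
      x <- stats::rhyper(L, cnt, remaining_pool - cnt, remaining_draw)
    } else {
      x <- remaining_draw
    }
    draws[, j] <- x
    remaining_pool <- remaining_pool - cnt
    remaining_draw <- remaining_draw - x
  }
  ac <- as.integer(rowSums(draws > 0L))
  maf <- rep(NA_real_, L)
  bi <- which(ac == 2L)
  if (length(bi)) {
    mn <- apply(draws[bi, , drop = FALSE], 1L, function(v) min(v[v > 0L]))
    maf[bi] <- mn / n
  }
  site_table(ac, sites$circular, sample_counts = draws, maf = maf)
}

#' Detection power versus sample size by allele downsampling
#'
#' For each sample size: downsample the allele counts, retrain the
#' allele-count HMM with the same fixed transitions and restart protocol,
#' call elements, and score them against a reference element set. Power is
#' the fraction of reference-constrained bp recovered (base-level recall);
#' precision and F1 are reported alongside. Values are averaged over
#' `replicates` independent downsamplings per size.
#'
#' @param sites a [site_table] with `sample_counts`.
#' @param reference_elements an [element_set] (simulation truth, or
#'   divergence-based calls).
#' @param sizes sample-size grid; default 100 to 1,800 by 100 plus 1,864.
#' @param transition fixed transition matrix passed to [mitopopcons()].
#' @param n_restarts,tol,max_iter training controls, as in [mitopopcons()].
#' @param replicates independent downsamplings per size.
#' @param seed integer seed; each (size, replicate) derives its own.
#' @param coupled if `TRUE` (default) the subsamples within a replicate are
#'   nested across sizes — each size's draw is a further subsample of the
#'   next larger one. Drawing without replacement from a without-replacement
#'   draw is distributionally identical to drawing from the full sample, so
#'   per-size marginals are unchanged; the coupling (common random numbers)
#'   removes most between-size Monte-Carlo noise, the right construction
#'   for estimating a monotone curve. `FALSE` draws each size independently.
#' @return an object of class `power_curve`: data.frame with columns
#'   `size`, `power` (mean recall), `precision`, `f1`, `sd_power`, plus
#'   attributes `replicates` and `seed`.
#' @export
power_curve <- function(sites, reference_elements,
                        sizes = c(seq(100L, 1800L, by = 100L), 1864L),
                        transition = phastcons_transition(),
                        n_restarts = 10L, tol = 1e-6, max_iter = 500L,
                        replicates = 3L, seed = 1L, coupled = TRUE) {
  stopifnot(inherits(sites, "site_table"))
  sizes <- sort(as.integer(sizes))
  K <- length(sizes)
  ref_bp <- sum(reference_elements$end - reference_elements$start)
  if (!ref_bp) stop("reference element set is empty")
  rec <- prec <- matrix(NA_real_, K, replicates)
  for (r in seq_len(replicates)) {
    cur <- sites
    for (i in rev(seq_len(K))) {
      sub_seed <- seed + 1000L * i + r
      cur <- downsample_alleles(if (coupled) cur else sites, sizes[i],
                                seed = sub_seed)
      fit <- mitopopcons(cur, transition = transition,
                         n_restarts = n_restarts, seed = sub_seed,
                         tol = tol, max_iter = max_iter)
      ov <- overlap_bp(fit$elements, reference_elements)
      called_bp <- sum(fit$elements$end - fit$elements$start)
      rec[i, r] <- ov / ref_bp
      prec[i, r] <- if (called_bp) ov / called_bp else NA_real_
    }
  }
  rows <- lapply(seq_len(K), function(i) {
    p <- mean(rec[i, ]); q <- mean(prec[i, ], na.rm = TRUE)
    data.frame(size = sizes[i], power = p,
               precision = if (is.nan(q)) NA_real_ else q,
               f1 = if (!is.na(q) && (p + q) > 0) 2 * p * q / (p + q) else 0,
               sd_power = stats::sd(rec[i, ]))
  })
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  attr(out, "metric") <- "base-level recall of reference-constrained bp"
  class(out) <- c("power_curve", "data.frame")
  out
}

#' @export
plot.power_curve <- function(x, ...) {
  graphics::plot(x$size, x$power, log = "x", type = "b", pch = 16,
                 xlab = "sample size (chromosomes)",
                 ylab = "power (recall of constrained bp)", ylim = c(0, 1), ...)
  invisible(x)
}
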