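#' Configuration for the synthetic mitochondrial-like dataset
#'
#' The generator is a deliberate caricature of an ultradeeply sampled
#' circular mitochondrial genome: sites are independent, the number of
#' segregating mutations at site i is Poisson with rate
#' `mu_i = theta_neutral * (1 - c_i) * exp(dssh_effect * D_ssH(i))`
#' (constraint `c_i` in \[0,1\]; D_ssH from the strand-displacement
#' replication model), each mutation's derived-allele count is drawn from
#' the neutral frequency spectrum `P(k) proportional to 1/k`, and
#' between-species divergence tracks are statistically coupled to the same
#' constraint. Real mtDNA shares a single non-recombining genealogy across
#' sites; the analyses under test treat sites marginally, so independent
#' sites give clean, assertable statistics.
#'
#' @param genome_length genome size in bp (default 16,569).
#' @param n_samples sampled chromosomes per site (default 16,411).
#' @param seed integer seed; sub-stages use fixed offsets from it.
#' @param origin_h,origin_l replication origin positions (0-based).
#' @param theta_neutral expected segregating mutations per neutral site.
#' @param dssh_effect multiplicative log-rate slope per bp-time of D_ssH.
#' @param divergence_scale scale `a` of the negated-phyloP-like track
#'   `a * (1 - c) + Normal(0, divergence_noise_sd)`.
#' @param divergence_noise_sd Gaussian noise sd on the score scale.
#' @param logistic_slope slope `b` of the conservation probability
#'   `plogis(b * (c - 0.5))`.
#' @param sfs_truncation largest derived-allele count drawn from the 1/k
#'   spectrum. The default, ~0.025% of the sample, emulates the rare-variant
#'   excess of an expanded population; it is what makes the number of
#'   recovered alleles (and hence detection power) grow with subsample
#'   size across the downsampling grid instead of saturating.
#' @param constrained_freq_cap maximum derived-allele frequency under
#'   constraint (`c > 0.5`): derived counts are drawn from the 1/k
#'   spectrum truncated at `constrained_freq_cap * (n_samples - 1)`
#'   (at least 1 copy; default 2e-4), so selection holds deleterious
#'   alleles markedly rarer than the neutral spectrum allows.
#' @param class_constraint named constraint levels per gene class for the
#'   block layout.
#' @param codon_modulation if `TRUE` (default), protein-gene sites are
#'   re-assigned codon-position-specific constraint from
#'   `codon_constraint`, so gene-level and codon-class correlations have
#'   within-gene contrast to detect.
#' @param codon_constraint named constraint per codon class. The default
#'   keeps every protein-coding position above the functional threshold
#'   (four-fold degenerate sites at 0.55: weakly but genuinely
#'   constrained, as mitochondrial synonymous sites are), so truth
#'   elements stay contiguous gene blocks; lower the four-fold level
#'   (e.g. to 0.1) for analyses that need strong synonymous/nonsynonymous
#'   contrast at the cost of fragmenting element truth.
#' @param functional_threshold truth elements are the maximal runs with
#'   `c > functional_threshold`.
#' @param control_length length of the control-region block at the origin
#'   of the coordinate system.
#' @param circular logical flag.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = 16569L,
                             n_samples = 16411L,
                             seed = 1L,
                             origin_h = 550L,
                             origin_l = 5780L,
                             theta_neutral = 1.8,
                             dssh_effect = 5e-5,
                             divergence_scale = 2,
                             divergence_noise_sd = 0.5,
                             logistic_slope = 6,
                             sfs_truncation = max(2L, round(2.5e-4 * n_samples)),
                             constrained_freq_cap = 2e-4,
                             class_constraint = c(protein = 0.8, tRNA = 0.9,
                                                  rRNA = 0.9, control = 0.2,
                                                  other = 0),
                             codon_modulation = TRUE,
                             codon_constraint = c(first = 0.8,
                                                  second_codon_position = 0.9,
                                                  fourfold_degenerate = 0.55,
                                                  other_third = 0.7),
                             functional_threshold = 0.5,
                             control_length = 1100L,
                             circular = TRUE) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_samples = as.integer(n_samples),
              seed = as.integer(seed),
              origin_h = as.integer(origin_h),
              origin_l = as.integer(origin_l),
              theta_neutral = theta_neutral,
              dssh_effect = dssh_effect,
              divergence_scale = divergence_scale,
              divergence_noise_sd = divergence_noise_sd,
              logistic_slope = logistic_slope,
              sfs_truncation = as.integer(sfs_truncation),
              constrained_freq_cap = constrained_freq_cap,
              class_constraint = class_constraint,
              codon_modulation = isTRUE(codon_modulation),
              codon_constraint = codon_constraint,
              functional_threshold = functional_threshold,
              control_length = as.integer(control_length),
              circular = isTRUE(circular))
  if (cfg$theta_neutral <= 0) stop("theta_neutral must be > 0")
  if (any(cfg$class_constraint < 0) || any(cfg$class_constraint > 1))
    stop("constraint levels must lie in [0, 1]")
  if (cfg$control_length >= cfg$genome_length) stop("control region exceeds genome")
  if (cfg$sfs_truncation < 1L || cfg$sfs_truncation > cfg$n_samples - 1L)
    stop("sfs_truncation must lie in 1..n_samples-1")
  structure(cfg, class = "synthetic_config")
}

#' Generate the synthetic gene layout, constraint truth and reference
#'
#' Tiles the circular genome with a mitochondrial-like mosaic: a control
#' region at the coordinate origin, two rRNA genes, and alternating
#' tRNA/protein genes with occasional short intergenic spacers. Assigns
#' per-site constraint from the class levels (optionally codon-modulated
#' within protein genes), computes the per-site mutation rate with the
#' D_ssH gradient, and derives the true constrained elements as maximal
#' runs with constraint above the functional threshold.
#'
#' @param config a [synthetic_config].
#' @return list with `annotations` (an [annotation_set]), `truth` (list:
#'   per-site `constraint`, `mu`, `dssh`, true [element_set] `elements`,
#'   `reference` character sequence), and the `config`.
#' @export
generate_layout <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  L <- config$genome_length
  name <- character(); start <- integer(); end <- integer()
  strand <- character(); cls <- character()
  add <- function(n, s, e, st, cl) {
    if (e > L) stop("layout exceeds genome")
    name <<- c(name, n); start <<- c(start, s); end <<- c(end, e)
    strand <<- c(strand, st); cls <<- c(cls, cl)
  }
  counters <- c(protein = 0L, tRNA = 0L, rRNA = 0L)
  nm <- function(cl) {
    counters[cl] <<- counters[cl] + 1L
    sprintf("%s-%02d", c(protein = "PROT", tRNA = "TRNA", rRNA = "RRNA")[cl],
            counters[cl])
  }
  add("CTRL", 0L, config$control_length, "+", "control")
  pos <- config$control_length
  # rRNA blocks scale with the genome so toy genomes keep the class mix
  rscale <- L / 16569
  preamble <- list(c("tRNA", 69L), c("rRNA", round(954L * rscale)),
                   c("tRNA", 69L), c("rRNA", round(1559L * rscale)))
  for (p in preamble) {
    len <- min(as.integer(p[2]), L - pos)
    if (len < 30L) next
    add(nm(p[1]), pos, pos + len, "+", p[1]); pos <- pos + len
  }
  while (L - pos >= 150L) {
    u <- stats::runif(1)
    if (u < 0.40) {
      len <- sample(66:72, 1L)
      kind <- "tRNA"
    } else if (u < 0.90) {
      len <- 3L * sample(60:450, 1L)
      kind <- "protein"
    } else {
      pos <- pos + sample(20:80, 1L)   # intergenic spacer
      next
    }
    len <- min(len, L - pos)
    if (kind == "protein") len <- len - len %% 3L
    if (len < 30L) break
    st <- if (stats::runif(1) < 0.15) "-" else "+"
    add(nm(kind), pos, pos + len, st, kind)
    pos <- pos + len
  }
  ann <- annotation_set(name, start, end, strand, cls, L, config$circular)

  reference <- paste(sample(BASES, L, replace = TRUE), collapse = "")

  constraint <- rep(config$class_constraint[["other"]], L)
  for (i in seq_len(nrow(ann)))
    constraint[(ann$start[i] + 1L):ann$end[i]] <-
      config$class_constraint[[ann$class[i]]]
  if (config$codon_modulation) {
    sc <- suppressWarnings(classify_sites(ann, reference))
    cc <- config$codon_constraint
    constraint[sc == "second_codon_position"] <- cc[["second_codon_position"]]
    constraint[sc == "fourfold_degenerate"] <- cc[["fourfold_degenerate"]]
    # remaining coding sites: first vs non-fourfold third position
    oc <- which(sc == "other_coding")
    if (length(oc)) {
      pos_of <- rep(NA_integer_, L)
      for (i in which(ann$class == "protein")) {
        span <- (ann$start[i] + 1L):ann$end[i]
        len <- length(span); usable <- len - len %% 3L
        if (!usable) next
        if (ann$strand[i] == "+") ordspan <- span[seq_len(usable)]
        else ordspan <- rev(span[(len - usable + 1L):len])
        pos_of[ordspan] <- rep(1:3, length.out = usable)
      }
      constraint[oc] <- ifelse(pos_of[oc] == 1L, cc[["first"]],
                               cc[["other_third"]])
    }
  }

  model <- replication_model(L, config$origin_h, config$origin_l)
  dssh <- compute_dssh(model)          # unmasked: the mutational truth
  mu <- config$theta_neutral * (1 - constraint) *
    exp(config$dssh_effect * dssh)

  above <- constraint > config$functional_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  truth_elements <- element_set(starts[r$values], ends[r$values], L,
                                label = "true_constrained",
                                source = "synthetic_truth")
  list(annotations = ann,
       truth = list(constraint = constraint, mu = mu, dssh = dssh,
                    elements = truth_elements, reference = reference),
       config = config)
}

# Derived-allele counts from the truncated 1/k neutral frequency spectrum
draw_sfs <- function(n_draw, kmax) {
  if (n_draw == 0L) return(integer(0))
  sample.int(kmax, n_draw, replace = TRUE, prob = 1 / seq_len(kmax))
}

#' Simulate per-site allele sample counts
#'
#' Per site, the number of segregating mutations is Poisson(`mu_i`); each
#' mutation becomes a distinct non-reference nucleotide whose carrier
#' count is drawn from the truncated 1/k spectrum (capped at the
#' frequency `constrained_freq_cap` when `c_i > 0.5`, mimicking
#' selection shifting frequencies down). The distinct-allele count is
#' `min(1 + m_i, 4)`; remaining chromosomes carry the reference allele.
#'
#' @param config a [synthetic_config].
#' @param truth the `truth` component of [generate_layout()].
#' @return a [site_table] with `sample_counts` and `maf`.
#' @export
simulate_site_alleles <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  L <- config$genome_length
  n <- config$n_samples
  ref <- strsplit(truth$reference, "")[[1]]
  m <- stats::rpois(L, truth$mu)
  m_eff <- pmin(m, 3L)
  kmax_full <- config$sfs_truncation
  kmax_cap <- min(kmax_full, max(1L, floor(config$constrained_freq_cap * (n - 1L))))
  capped <- truth$constraint > 0.5

  counts <- matrix(0L, L, 4L, dimnames = list(NULL, BASES))
  ref_col <- match(ref, BASES)
  counts[cbind(seq_len(L), ref_col)] <- n

  poly <- which(m_eff > 0L)
  # draw all derived counts up front (one stream per cap regime)
  k_full <- draw_sfs(sum(m_eff[poly][!capped[poly]]), kmax_full)
  k_cap <- draw_sfs(sum(m_eff[poly][capped[poly]]), kmax_cap)
  i_full <- 0L; i_cap <- 0L
  for (s in poly) {
    mm <- m_eff[s]
    if (capped[s]) { ks <- k_cap[i_cap + seq_len(mm)]; i_cap <- i_cap + mm }
    else { ks <- k_full[i_full + seq_len(mm)]; i_full <- i_full + mm }
    # keep at least one reference chromosome; clip the largest draws down
    while (sum(ks) > n - 1L) {
      j <- which.max(ks)
      ks[j] <- max(1L, ks[j] - (sum(ks) - (n - 1L)))
      if (sum(ks) > n - 1L && all(ks == 1L)) { ks <- ks[-j]; }
    }
    alts <- sample(setdiff(BASES, ref[s]), length(ks))
    counts[s, alts] <- ks
    counts[s, ref[s]] <- n - sum(ks)
  }
  ac <- as.integer(rowSums(counts > 0L))
  maf <- rep(NA_real_, L)
  bi <- which(ac == 2L)
  if (length(bi)) {
    mn <- apply(counts[bi, , drop = FALSE], 1L, function(v) min(v[v > 0L]))
    maf[bi] <- mn / n
  }
  site_table(ac, config$circular, sample_counts = counts, maf = maf)
}

#' Simulate divergence score tracks coupled to the constraint truth
#'
#' The negated-phyloP-like track is `a * (1 - c_i)` plus Gaussian noise
#' (larger = more divergent); the phastCons-like conservation probability
#' is the deterministic logistic `plogis(b * (c_i - 0.5))`.
#'
#' @inheritParams simulate_site_alleles
#' @return list with `negated_phylop` and `conservation` [score_track]s.
#' @export
simulate_divergence <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  c_i <- truth$constraint
  neg <- config$divergence_scale * (1 - c_i) +
    stats::rnorm(length(c_i), 0, config$divergence_noise_sd)
  prob <- stats::plogis(config$logistic_slope * (c_i - 0.5))
  prob <- pmin(pmax(prob, 0), 1)
  list(negated_phylop = score_track(neg, "negated_phylop"),
       conservation = score_track(prob, "conservation_probability"))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the SNP table (counts dialect), a phyloP-like wiggle track (the
#' negated simulated track re-negated, so the file follows the usual
#' larger-= -more-conserved convention), a conservation-probability
#' bedGraph, the gene annotation BED, the truth element BED, the reference
#' FASTA, and a JSON manifest with the seed, the full configuration and
#' per-file MD5 hashes. Regeneration with the same seed is byte-identical.
#'
#' @param config a [synthetic_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
emit_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lay <- generate_layout(config)
  sites <- simulate_site_alleles(config, lay$truth)
  div <- simulate_divergence(config, lay$truth)
  paths <- list(
    snps = file.path(out_dir, "snps.tsv"),
    phylop = file.path(out_dir, "phylop.wig"),
    conservation = file.path(out_dir, "conservation.bedgraph"),
    annotations = file.path(out_dir, "genes.bed"),
    truth_elements = file.path(out_dir, "truth_elements.bed"),
    reference = file.path(out_dir, "reference.fa"))
  write_snp_table(sites, paths$snps, "positions_with_counts")
  write_score_track(negate_track(div$negated_phylop), paths$phylop, "wig")
  write_score_track(div$conservation, paths$conservation, "bedgraph")
  write_annotations(lay$annotations, paths$annotations)
  write_elements(lay$truth$elements, paths$truth_elements)
  dna <- Biostrings::DNAStringSet(lay$truth$reference)
  names(dna) <- "chrM_synthetic"
  Biostrings::writeXStringSet(dna, paths$reference)
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   files = lapply(paths, basename),
                   md5 = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
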