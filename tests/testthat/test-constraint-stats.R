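test_that("spearman handles perfect, reversed and tied inputs", {
  expect_equal(spearman_cor(1:3, 1:3)$rho, 1)
  expect_equal(spearman_cor(1:3, 3:1)$rho, -1)
  r <- spearman_cor(c(1, 1, 2, 2, 3), c(2, 1, 4, 4, 5))
  expect_equal(r$rho, naive_spearman(c(1, 1, 2, 2, 3), c(2, 1, 4, 4, 5)),
               tolerance = 1e-12)
  expect_true(r$ties)
  expect_warning(rz <- spearman_cor(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(rz$rho))
})

test_that("spearman equals the brute-force midrank implementation", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    x <- sample(1:5, n, replace = TRUE)           # heavy ties
    y <- sample(1:5, n, replace = TRUE) + rnorm(n, 0, 0.01)
    r <- suppressWarnings(spearman_cor(x, y))
    if (is.na(r$rho)) next
    expect_equal(r$rho, naive_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("spearman is symmetric and monotone-invariant", {
  set.seed(102)
  for (rep in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- rnorm(30)
    a <- spearman_cor(x, y)$rho
    expect_identical(a, spearman_cor(y, x)$rho)
    expect_equal(spearman_cor(exp(x), y)$rho, a)           # monotone in x
    expect_equal(spearman_cor(x, 5 * y - 2)$rho, a)        # affine in y
    expect_equal(spearman_cor(x, pmin(exp(y), 1e6))$rho, a)
  }
})

test_that("spearman p-values match the t approximation convention", {
  set.seed(103)
  x <- rnorm(50); y <- x + rnorm(50, 0, 2)
  r <- spearman_cor(x, y)
  tstat <- r$rho * sqrt((r$n - 2) / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), r$n - 2))
  # reports floor small p at the conventional threshold, raw value kept
  big <- spearman_cor(1:1000, 1:1000 + rnorm(1000, 0, 1e-3))
  expect_lt(big$p_value, 2.2e-16)
  expect_output(print(big), "< 2.2e-16")
})

test_that("window averages follow adjacent, trailing and circular rules", {
  expect_equal(window_average(rep(3, 25), 10), c(3, 3, 3))  # trailing 5 < w/2? 5 >= 5 kept
  expect_equal(length(window_average(rep(1, 30), 10, 10)), 3L)
  v <- c(1, 2, 3, 4, 5, 6)
  # width 5, step 1, circular: manual wraparound means
  want <- c(mean(v[c(1:5)]), mean(v[c(2:6)]), mean(v[c(3:6, 1)]),
            mean(v[c(4:6, 1:2)]), mean(v[c(5:6, 1:3)]), mean(v[c(6, 1:4)]))
  expect_equal(window_average(v, 5, 1, circular = TRUE), want)
  # width 1, step 1 is the identity
  expect_equal(window_average(v, 1, 1), v)
  # masked sites drop out of the mean
  expect_equal(window_average(c(1, NA, 3, 5, NA, NA), 3, 3), c(2, 5))
  expect_error(window_average(1:5, 10), "width")
  # trailing window shorter than half a window is dropped
  expect_equal(length(window_average(rep(1, 23), 10, 10)), 2L)
  expect_equal(length(window_average(rep(1, 25), 10, 10)), 3L)
})

test_that("per-gene table mirrors the gene-level analysis", {
  cfg <- synthetic_config(genome_length = 3000L, n_samples = 1000L, seed = 41L,
                          control_length = 250L, origin_h = 60L,
                          origin_l = 1600L)
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  div <- simulate_divergence(cfg, lay$truth)
  tab <- per_gene_correlations(st, div$negated_phylop, lay$annotations)
  expect_equal(nrow(tab), nrow(lay$annotations))
  expect_true(all(c("name", "description", "start", "end", "rho", "p",
                    "rho_corrected", "p_corrected") %in% names(tab)))
  expect_true(all(is.na(tab$rho) | (tab$rho >= -1 & tab$rho <= 1)))
  expect_identical(attr(tab, "n_genes"), nrow(tab))
  expect_lte(attr(tab, "n_significant"), nrow(tab))
  # corrected columns appear when residuals are supplied
  m <- replication_model(3000, 60, 1600, control_region = c(0, 250))
  dssh <- dssh_track(m); use <- !is.na(dssh)
  fit <- fit_poisson_glm(st$allele_count[use], dssh[use])
  res <- rep(NA_real_, 3000); res[use] <- residuals(fit)
  tab2 <- per_gene_correlations(st, div$negated_phylop, lay$annotations,
                                residuals = res)
  expect_true(any(!is.na(tab2$rho_corrected)))
})

test_that("gene-level correlations exceed the neutral background", {
  # constraint only inside genes: the control region is neutral here
  cfg <- synthetic_config(genome_length = 8000L, n_samples = 4000L,
                          seed = 47L, control_length = 1500L, origin_h = 60L,
                          origin_l = 4500L,
                          class_constraint = c(protein = 0.8, tRNA = 0.9,
                                               rRNA = 0.9, control = 0,
                                               other = 0))
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  div <- simulate_divergence(cfg, lay$truth)
  tab <- per_gene_correlations(st, div$negated_phylop, lay$annotations)
  prot <- abs(tab$rho[grepl("PROT", tab$name)])
  neutral_idx <- 1:1500   # the unconstrained control region
  r0 <- suppressWarnings(
    spearman_cor(st$allele_count[neutral_idx],
                 div$negated_phylop$values[neutral_idx]))
  expect_gt(median(prot, na.rm = TRUE), abs(r0$rho))
  expect_gt(median(prot, na.rm = TRUE), 0.05)
})

test_that("a gene of monomorphic sites gets an undefined correlation", {
  ann <- annotation_set("g1", 10, 40, "+", "tRNA", 100)
  st <- site_table(rep(1L, 100))
  tab <- per_gene_correlations(st, rnorm(100), ann)
  expect_true(is.na(tab$rho[1]))
})

test_that("codon classes follow the vertebrate mitochondrial code", {
  # one + strand gene covering positions 10..27 (6 codons)
  L <- 40
  seqs <- paste(rep("A", L), collapse = "")
  # codons: CTA CTG ATA ATT GGC TAA
  substr(seqs, 11, 28) <- "CTACTGATAATTGGCTAA"
  ann <- annotation_set("g", 10, 28, "+", "protein", L)
  lab <- classify_sites(ann, seqs)
  expect_equal(lab[12], "second_codon_position")      # middle of CTA
  expect_equal(lab[13], "fourfold_degenerate")        # CTx all Leu
  expect_equal(lab[16], "fourfold_degenerate")        # CTG third base
  expect_equal(lab[19], "other_coding")               # ATx: Met vs Ile
  expect_equal(lab[25], "fourfold_degenerate")        # GGx all Gly
  expect_equal(lab[28], "other_coding")               # TAx: stop vs Tyr
  expect_equal(sum(lab == "second_codon_position"), 6L)
  expect_true(all(lab[c(1:10, 29:40)] == "noncoding_other"))
})

test_that("minus-strand genes are read on the reverse complement", {
  L <- 30
  s <- paste(rep("G", L), collapse = "")
  # genome 10..18 holds TAG GGT ACC; reverse complement read 5'->3' is
  # GGT ACC CTA: codon1 GGT (fourfold GGx), codon3 CTA (fourfold CTx)
  substr(s, 11, 19) <- "TAGGGTACC"
  ann <- annotation_set("g", 10, 19, "-", "protein", L)
  lab <- classify_sites(ann, s)
  # third base of GGT codon is genome position 11 (0-based 10... reading
  # backwards): reading order is genome indices 19,18,...,11
  # codon1 = pos 19,18,17 -> third at 17; codon2 = 16,15,14; codon3 = 13,12,11
  expect_equal(lab[17], "fourfold_degenerate")
  expect_equal(lab[18], "second_codon_position")
  expect_equal(lab[11], "fourfold_degenerate")
  expect_equal(lab[12], "second_codon_position")
})

test_that("control region, RNA genes and partial codons are labelled", {
  L <- 60
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  ann <- annotation_set(c("ctrl", "t1", "p1"), c(0, 10, 20), c(10, 18, 30),
                        c("+", "+", "+"), c("control", "tRNA", "protein"), L)
  expect_warning(lab <- classify_sites(ann, s), "partial codon")
  expect_true(all(lab[1:10] == "noncoding_control"))
  expect_true(all(lab[11:18] == "rna_gene"))
  expect_true(all(lab[21:29] != "noncoding_other"))   # 3 full codons
  expect_equal(lab[30], "noncoding_other")            # skipped partial codon
  expect_equal(sum(lab[21:29] == "second_codon_position"), 3L)
})

test_that("codon-modulated synthetic data separates codon classes", {
  cfg <- synthetic_config(genome_length = 6000L, n_samples = 2000L, seed = 51L,
                          control_length = 300L, origin_h = 50L,
                          origin_l = 3300L, codon_modulation = TRUE)
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  lab <- suppressWarnings(classify_sites(lay$annotations, lay$truth$reference))
  second <- st$allele_count[lab == "second_codon_position"]
  fourfold <- st$allele_count[lab == "fourfold_degenerate"]
  # constrained nonsynonymous sites are far less polymorphic
  expect_lt(mean(second > 1), mean(fourfold > 1) - 0.2)
})

test_that("MAF correlates with divergence under constraint frequency capping", {
  # balanced constrained/unconstrained mix so the frequency cap has
  # something to contrast against
  cfg <- synthetic_config(genome_length = 10000L, n_samples = 5000L,
                          seed = 61L, control_length = 2500L, origin_h = 80L,
                          origin_l = 5500L,
                          class_constraint = c(protein = 0.9, tRNA = 0.9,
                                               rRNA = 0.9, control = 0.05,
                                               other = 0))
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  div <- simulate_divergence(cfg, lay$truth)
  r <- maf_divergence_correlation(st, div$negated_phylop)
  expect_gt(r$rho, 0)
  expect_lt(r$p_value, 0.01)
  # degenerate cases
  st0 <- site_table(rep(1L, 100), maf = rep(NA_real_, 100))
  expect_warning(r0 <- maf_divergence_correlation(st0, rnorm(100)), "biallelic")
  expect_true(is.na(r0$rho))
  maf_const <- rep(NA_real_, 100); maf_const[1:10] <- 0.2
  ac <- rep(1L, 100); ac[1:10] <- 2L
  stc <- site_table(ac, maf = maf_const)
  expect_warning(rc <- maf_divergence_correlation(stc, rnorm(100)),
                 "zero variance")
  expect_true(is.na(rc$rho))
})
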