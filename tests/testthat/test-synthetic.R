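small_cfg <- function(..., seed = 5L) {
  synthetic_config(genome_length = 2000L, n_samples = 2000L, seed = seed,
                   control_length = 200L, origin_h = 50L, origin_l = 900L, ...)
}

test_that("layout tiles the genome consistently with the constraint truth", {
  cfg <- small_cfg()
  lay <- generate_layout(cfg)
  ann <- lay$annotations
  expect_s3_class(ann, "annotation_set")
  expect_true(all(ann$end <= cfg$genome_length))
  # annotated + intergenic bp account for the whole genome
  cov <- logical(cfg$genome_length)
  for (i in seq_len(nrow(ann))) cov[(ann$start[i] + 1):ann$end[i]] <- TRUE
  expect_equal(sum(ann$end - ann$start), sum(cov))  # no overlaps
  expect_equal(sum(cov) + sum(!cov), cfg$genome_length)
  # truth elements are exactly the maximal runs above the threshold
  above <- lay$truth$constraint > cfg$functional_threshold
  r <- rle(above)
  expect_equal(nrow(lay$truth$elements), sum(r$values))
  expect_equal(sum(lay$truth$elements$end - lay$truth$elements$start),
               sum(above))
  # mutation rate follows mu = theta * (1 - c) * exp(effect * dssh)
  expect_equal(lay$truth$mu,
               cfg$theta_neutral * (1 - lay$truth$constraint) *
                 exp(cfg$dssh_effect * lay$truth$dssh))
})

test_that("fully constrained and unconstrained limits behave", {
  cfg <- small_cfg(class_constraint = c(protein = 1, tRNA = 1, rRNA = 1,
                                        control = 1, other = 1),
                   codon_modulation = FALSE)
  lay <- generate_layout(cfg)
  expect_true(all(lay$truth$mu == 0))
  st <- simulate_site_alleles(cfg, lay$truth)
  expect_equal(st$allele_count, rep(1L, cfg$genome_length))

  cfg0 <- small_cfg(class_constraint = c(protein = 0, tRNA = 0, rRNA = 0,
                                         control = 0, other = 0),
                    codon_modulation = FALSE)
  lay0 <- generate_layout(cfg0)
  expect_equal(nrow(lay0$truth$elements), 0L)
})

test_that("monomorphic fraction matches the Poisson zero class", {
  # constant mu: constraint 0 everywhere, no dssh effect
  cfg <- synthetic_config(genome_length = 20000L, n_samples = 500L, seed = 9L,
                          control_length = 100L, origin_h = 5L,
                          origin_l = 9000L, theta_neutral = 0.7,
                          dssh_effect = 0,
                          class_constraint = c(protein = 0, tRNA = 0,
                                               rRNA = 0, control = 0,
                                               other = 0),
                          codon_modulation = FALSE)
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  p_mono <- mean(st$allele_count == 1L)
  expected <- exp(-0.7)
  mc_sd <- sqrt(expected * (1 - expected) / cfg$genome_length)
  expect_lt(abs(p_mono - expected), 3 * mc_sd)
  expect_true(all(st$allele_count <= 4L))
  expect_equal(unname(rowSums(st$sample_counts)), rep(500, 20000))
})

test_that("allele counts never exceed 4 even at extreme mutation rates", {
  cfg <- small_cfg(theta_neutral = 50, codon_modulation = FALSE,
                   class_constraint = c(protein = 0, tRNA = 0, rRNA = 0,
                                        control = 0, other = 0))
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  expect_true(all(st$allele_count <= 4L))
  expect_true(all(st$allele_count >= 1L))
})

test_that("increasing constraint never increases expected polymorphism", {
  base <- c(protein = 0.3, tRNA = 0.3, rRNA = 0.3, control = 0.3, other = 0.3)
  high <- base + 0.5
  polym <- vapply(list(base, high), function(cc) {
    cfg <- small_cfg(class_constraint = cc, codon_modulation = FALSE)
    lay <- generate_layout(cfg)
    mean(simulate_site_alleles(cfg, lay$truth)$allele_count > 1L)
  }, numeric(1))
  expect_gt(polym[1], polym[2])
})

test_that("divergence tracks are coupled to constraint", {
  cfg <- small_cfg(divergence_noise_sd = 0)
  lay <- generate_layout(cfg)
  div <- simulate_divergence(cfg, lay$truth)
  # noise-free: negated score is a strictly decreasing function of c
  r <- spearman_cor(div$negated_phylop$values, 1 - lay$truth$constraint)
  expect_equal(r$rho, 1)
  expect_true(all(div$conservation$values >= 0 & div$conservation$values <= 1))
  # fully constrained genome, no noise: constant minimum divergence
  cfg1 <- small_cfg(divergence_noise_sd = 0, codon_modulation = FALSE,
                    class_constraint = c(protein = 1, tRNA = 1, rRNA = 1,
                                         control = 1, other = 1))
  lay1 <- generate_layout(cfg1)
  div1 <- simulate_divergence(cfg1, lay1$truth)
  expect_equal(unique(div1$negated_phylop$values), 0)

  # default noise: polymorphism-divergence correlation is recoverable
  cfgn <- small_cfg()
  layn <- generate_layout(cfgn)
  stn <- simulate_site_alleles(cfgn, layn$truth)
  divn <- simulate_divergence(cfgn, layn$truth)
  rn <- spearman_cor(stn$allele_count, divn$negated_phylop$values)
  expect_gt(rn$rho, 0.05)
  expect_lt(rn$p_value, 1e-6)
})

test_that("emitted datasets are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_cfg()
  m1 <- emit_dataset(cfg, d1)
  m2 <- emit_dataset(cfg, d2)
  expect_equal(m1$md5, m2$md5)
  files <- setdiff(list.files(d1), "manifest.json")
  expect_setequal(files, setdiff(list.files(d2), "manifest.json"))
  for (f in files)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  # different seed changes the SNP table
  m3 <- emit_dataset(small_cfg(seed = 6L), d2)
  expect_false(identical(m2$md5$snps, m3$md5$snps))
  # manifest round-trips the configuration
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 5L)
  expect_equal(man$config$theta_neutral, cfg$theta_neutral)
  expect_equal(unlist(man$md5), unlist(lapply(m1$md5, unname)))
})

test_that("emitted files reload into equivalent objects", {
  d <- withr::local_tempdir()
  cfg <- small_cfg()
  emit_dataset(cfg, d)
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  div <- simulate_divergence(cfg, lay$truth)
  L <- cfg$genome_length
  back <- read_snp_table(file.path(d, "snps.tsv"), "positions_with_counts", L,
                         reference = lay$truth$reference)
  expect_equal(back$allele_count, st$allele_count)
  ph <- read_score_track(file.path(d, "phylop.wig"), "wig", "phylop", L)
  expect_equal(negate_track(ph)$values, div$negated_phylop$values,
               tolerance = 1e-5)  # %.6g formatting on disk
  ann <- read_annotations(file.path(d, "genes.bed"), L)
  expect_equal(ann$name, lay$annotations$name)
  tr <- read_elements(file.path(d, "truth_elements.bed"), L)
  expect_equal(tr$start, lay$truth$elements$start)
})
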