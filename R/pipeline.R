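PIPELINE_KEYS <- c("simulate", "inputs", "seed", "out_dir", "hmm",
                   "windows", "overlap", "power", "run_power")

#' Run the full analysis pipeline
#'
#' Orchestrates, with one configuration: (1) dataset simulation (or
#' loading from files), (2) D_ssH mutational-bias correction via the
#' Poisson GLM, (3) the correlation analyses (site-level, adjacent
#' windows, per-gene table, MAF-divergence), (4) allele-count HMM training
#' and element calling, and (5) evaluation (overlap permutation test
#' against divergence-derived elements, genic/intergenic summaries, and
#' optionally the downsampling power curve). All stages are seeded from
#' the configuration; a rerun with the same configuration is
#' byte-identical on disk.
#'
#' The configuration is a nested list (or a YAML file path) with keys:
#' \describe{
#'   \item{seed}{integer master seed.}
#'   \item{simulate}{arguments for [synthetic_config()] (a `seed` here
#'     overrides the master seed), or omit and supply `inputs`.}
#'   \item{inputs}{named file paths (`snps`, `phylop`, `conservation`,
#'     `annotations`, `reference`, optional `elements`) plus
#'     `genome_length`, `origin_h`, `origin_l`, `control_region`; used
#'     when no `simulate` block is given.}
#'   \item{hmm}{`expected_length`, `coverage`, `n_restarts`, `tol`,
#'     `max_iter`.}
#'   \item{windows}{`width` (default 10), `step` (default `width`),
#'     `circular` (default FALSE).}
#'   \item{overlap}{`n_perm` (default 10,000), `scheme`.}
#'   \item{run_power}{logical, default FALSE (the power stage retrains
#'     the HMM once per size and replicate).}
#'   \item{power}{`sizes`, `replicates` for [power_curve()].}
#' }
#' Unknown top-level keys are rejected.
#'
#' @param config nested list or path to a YAML file.
#' @param out_dir output directory; per-stage files and a JSON report and
#'   manifest are written there. `NULL` skips writing.
#' @return invisibly, a list with all stage results (`data`,
#'   `bias_correction`, `correlations`, `hmm_fit`, `evaluation`,
#'   `report`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- stage 1: data -------------------------------------------------
  if (!is.null(config$inputs)) {
    data <- load_pipeline_inputs(config$inputs)
  } else {
    sim_args <- config$simulate %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    scfg <- do.call(synthetic_config, sim_args)
    lay <- generate_layout(scfg)
    data <- list(sites = simulate_site_alleles(scfg, lay$truth),
                 tracks = simulate_divergence(scfg, lay$truth),
                 annotations = lay$annotations,
                 reference = lay$truth$reference,
                 truth = lay$truth,
                 genome_length = scfg$genome_length,
                 model = replication_model(scfg$genome_length, scfg$origin_h,
                                           scfg$origin_l,
                                           control_region = control_interval(lay$annotations)),
                 config = scfg)
  }
  L <- data$genome_length
  neg <- data$tracks$negated_phylop$values

  # ---- stage 2: D_ssH bias correction --------------------------------
  dssh <- dssh_track(data$model)
  use <- !is.na(dssh)
  fit <- fit_poisson_glm(data$sites$allele_count[use], dssh[use])
  resid_track <- rep(NA_real_, L)
  resid_track[use] <- residuals(fit)
  partial <- residual_partial_correlation(fit, neg[use])

  # ---- stage 3: correlations -----------------------------------------
  wcfg <- config$windows %||% list()
  width <- wcfg$width %||% 10L
  wstep <- wcfg$step %||% width
  wcirc <- wcfg$circular %||% FALSE
  site_rho <- spearman_cor(data$sites$allele_count, neg)
  dssh_rho <- spearman_cor(dssh[use], neg[use])
  win_rho <- spearman_cor(
    window_average(as.numeric(data$sites$allele_count), width, wstep, wcirc),
    window_average(neg, width, wstep, wcirc))
  gene_tab <- per_gene_correlations(data$sites, neg, data$annotations,
                                    residuals = resid_track)
  maf_rho <- if (!is.null(data$sites$maf))
    suppressWarnings(maf_divergence_correlation(data$sites, neg)) else NULL
  site_classes <- if (!is.null(data$reference))
    suppressWarnings(classify_sites(data$annotations, data$reference)) else NULL
  correlations <- list(site = site_rho, windowed = win_rho,
                       site_corrected = partial, dssh_divergence = dssh_rho,
                       per_gene = gene_tab, maf = maf_rho,
                       site_classes = site_classes)

  # ---- stage 4: HMM --------------------------------------------------
  hcfg <- config$hmm %||% list()
  transition <- phastcons_transition(hcfg$expected_length %||% 100,
                                     hcfg$coverage %||% 0.5)
  hmm_fit <- mitopopcons(data$sites, transition = transition,
                         n_restarts = hcfg$n_restarts %||% 10L,
                         seed = seed,
                         tol = hcfg$tol %||% 1e-6,
                         max_iter = hcfg$max_iter %||% 500L)

  # ---- stage 5: evaluation -------------------------------------------
  ocfg <- config$overlap %||% list()
  div_elements <- data$elements %||%
    conservation_elements(data$tracks$conservation, L)
  ov <- permutation_overlap_test(hmm_fit$elements, div_elements,
                                 n_perm = ocfg$n_perm %||% 10000L,
                                 scheme = ocfg$scheme %||% "independent_uniform_circular",
                                 seed = seed)
  summ <- summarize_elements(hmm_fit$elements, data$annotations)
  truth_eval <- if (!is.null(data$truth)) {
    ovt <- overlap_bp(hmm_fit$elements, data$truth$elements)
    tbp <- sum(data$truth$elements$end - data$truth$elements$start)
    cbp <- sum(hmm_fit$elements$end - hmm_fit$elements$start)
    list(recall = ovt / tbp,
         precision = if (cbp) ovt / cbp else NA_real_,
         false_positive_bp = cbp - ovt, truth_bp = tbp, called_bp = cbp)
  }
  pw <- NULL
  if (isTRUE(config$run_power)) {
    pcfg <- config$power %||% list()
    pw <- power_curve(data$sites,
                      data$truth$elements %||% div_elements,
                      sizes = pcfg$sizes %||% c(seq(100L, 1800L, 100L), 1864L),
                      transition = transition,
                      n_restarts = hcfg$n_restarts %||% 10L,
                      replicates = pcfg$replicates %||% 3L,
                      seed = seed)
  }
  evaluation <- list(overlap_test = ov, element_summary = summ,
                     truth = truth_eval, power = pw,
                     divergence_elements = div_elements)

  report <- pipeline_report(correlations, hmm_fit, evaluation, seed)
  if (!is.null(out_dir))
    write_pipeline_outputs(out_dir, data, fit, resid_track, correlations,
                           hmm_fit, evaluation, report, seed)
  invisible(list(data = data, bias_correction = list(fit = fit,
                                                     residuals = resid_track,
                                                     dssh = dssh),
                 correlations = correlations, hmm_fit = hmm_fit,
                 evaluation = evaluation, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

control_interval <- function(annotations) {
  ctrl <- annotations[annotations$class == "control", , drop = FALSE]
  if (!nrow(ctrl)) return(NULL)
  c(min(ctrl$start), max(ctrl$end))
}

# threshold a conservation-probability track into divergence-based elements
conservation_elements <- function(track, genome_length, threshold = 0.5) {
  stopifnot(inherits(track, "score_track"))
  above <- !is.na(track$values) & track$values > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  element_set(starts[r$values], ends[r$values], genome_length,
              label = "conserved", source = "conservation_track")
}

load_pipeline_inputs <- function(inputs) {
  L <- as.integer(inputs$genome_length)
  ann <- read_annotations(inputs$annotations, L)
  reference <- NULL
  if (!is.null(inputs$reference)) {
    fa <- Biostrings::readDNAStringSet(inputs$reference)
    reference <- as.character(fa[[1]])
  }
  sites <- read_snp_table(inputs$snps,
                          dialect = inputs$snp_dialect %||% "positions_with_counts",
                          genome_length = L,
                          n_samples = inputs$n_samples,
                          reference = reference)
  phylop <- read_score_track(inputs$phylop, "wig", "phylop", L)
  cons <- read_score_track(inputs$conservation, "bedgraph",
                           "conservation_probability", L)
  elements <- if (!is.null(inputs$elements))
    read_elements(inputs$elements, L, source = "divergence_input")
  cr <- if (!is.null(inputs$control_region)) as.integer(inputs$control_region)
        else control_interval(ann)
  list(sites = sites,
       tracks = list(negated_phylop = negate_track(phylop), conservation = cons),
       annotations = ann, reference = reference, truth = NULL,
       elements = elements, genome_length = L,
       model = replication_model(L, as.integer(inputs$origin_h),
                                 as.integer(inputs$origin_l),
                                 control_region = cr),
       config = NULL)
}

pipeline_report <- function(correlations, hmm_fit, evaluation, seed) {
  s <- summary(hmm_fit)
  list(seed = seed,
       correlations = list(
         site_rho = correlations$site$rho,
         site_p = correlations$site$p_value,
         windowed_rho = correlations$windowed$rho,
         site_rho_corrected = correlations$site_corrected$rho,
         dssh_divergence_rho = correlations$dssh_divergence$rho,
         maf_rho = if (!is.null(correlations$maf)) correlations$maf$rho,
         genes_significant = attr(correlations$per_gene, "n_significant"),
         genes_significant_corrected = attr(correlations$per_gene,
                                            "n_significant_corrected"),
         genes_total = attr(correlations$per_gene, "n_genes")),
       hmm = list(loglik = s$loglik, n_elements = s$n_elements,
                  mean_element_length = s$mean_element_length,
                  constrained_bp = s$constrained_bp,
                  emission = s$emission),
       evaluation = list(
         overlap_bp = evaluation$overlap_test$observed,
         overlap_p = evaluation$overlap_test$p_value,
         frac_intergenic_bp = evaluation$element_summary$frac_intergenic_bp,
         frac_genic_recovered = evaluation$element_summary$frac_genic_recovered,
         truth_recall = evaluation$truth$recall,
         truth_precision = evaluation$truth$precision,
         power = if (!is.null(evaluation$power))
           as.data.frame(evaluation$power)))
}

write_pipeline_outputs <- function(out_dir, data, fit, resid_track,
                                   correlations, hmm_fit, evaluation, report,
                                   seed) {
  write_elements(hmm_fit$elements, file.path(out_dir, "popcons_elements.bed"))
  write_elements(evaluation$divergence_elements,
                 file.path(out_dir, "divergence_elements.bed"))
  utils::write.table(correlations$per_gene,
                     file.path(out_dir, "per_gene_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  resid_df <- data.frame(position = seq_along(resid_track) - 1L,
                         residual = ifelse(is.na(resid_track), "NA",
                                           sprintf("%.6g", resid_track)))
  utils::write.table(resid_df, file.path(out_dir, "polymorphism_residuals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(seed = seed,
                   files = list.files(out_dir),
                   md5 = as.list(tools::md5sum(
                     file.path(out_dir, sort(setdiff(list.files(out_dir),
                                                     "manifest.json"))))))
  names(manifest$md5) <- basename(names(manifest$md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
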