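default_emissions <- function() {
  rbind(c(0.95, 0.04, 0.009, 0.001),    # functional: mostly monomorphic
        c(0.55, 0.30, 0.12, 0.03))      # nonfunctional
}

test_that("forward likelihood matches closed forms on tiny chains", {
  p <- hmm_params(diag(2), rbind(rep(0.25, 4), rep(0.25, 4)),
                  initial = c(0.3, 0.7))
  expect_equal(forward_loglik(p, 3L), log(0.25))
  # state-independent emissions: sites are independent, duplicating the
  # sequence doubles the log-likelihood
  e <- c(0.4, 0.3, 0.2, 0.1)
  p2 <- hmm_params(diag(2), rbind(e, e), initial = c(0.5, 0.5))
  obs <- c(1L, 1L, 2L)
  expect_equal(forward_loglik(p2, c(obs, obs)), 2 * forward_loglik(p2, obs),
               tolerance = 1e-10)
  expect_error(forward_loglik(p, c(1L, 5L)), "1..4")
})

test_that("forward and Viterbi agree with exhaustive path enumeration", {
  set.seed(202)
  for (rep in 1:100) {
    h <- random_hmm()
    T_ <- sample(1:9, 1)
    obs <- sample(1:4, T_, replace = TRUE)
    p <- hmm_params(h$trans, h$emis, h$init)
    expect_lt(abs(forward_loglik(p, obs) -
                    enum_forward(obs, h$trans, h$emis, h$init)), 1e-9)
    v <- viterbi_decode(p, obs)
    expect_lt(abs(v$logprob - enum_viterbi(obs, h$trans, h$emis, h$init)), 1e-9)
  }
})

test_that("Viterbi recovers deterministic and strongly biased paths", {
  em <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  p <- hmm_params(matrix(0.5, 2, 2), em, c(0.5, 0.5))
  expect_equal(viterbi_decode(p, c(1L, 1L, 2L, 2L, 1L))$path,
               c(1L, 1L, 2L, 2L, 1L))
  # uniform emissions, transitions strongly favoring state 1
  p2 <- hmm_params(rbind(c(0.999, 0.001), c(0.999, 0.001)),
                   rbind(rep(0.25, 4), rep(0.25, 4)), c(0.999, 0.001))
  expect_equal(unique(viterbi_decode(p2, sample(1:4, 50, TRUE))$path), 1L)
})

test_that("Baum-Welch freezes transitions and increases likelihood", {
  cfg <- synthetic_config(seed = 71L)
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  fit <- mitopopcons(st, seed = 13L)
  expect_length(fit$restarts$loglik, 10L)
  expect_equal(fit$loglik, max(fit$restarts$loglik))
  # monotone likelihood along the kept restart's trace
  expect_true(all(diff(fit$restarts$loglik_trace) >= -1e-8))
  # pseudocount freezing: trained transitions within 1e-6 of the fixed ones
  expect_lt(max(abs(fit$params$transition - fit$fixed_transition)), 1e-6)
  # initial distribution is the stationary distribution of the transitions
  expect_equal(fit$params$initial,
               stationary_distribution(fit$fixed_transition))
})

test_that("degenerate all-monomorphic data trains to a boundary with warning", {
  expect_warning(fit <- mitopopcons(rep(1L, 400), n_restarts = 2L, seed = 1L),
                 "identifiab")
  expect_gte(min(fit$params$emission[, 1]), 1 - 1e-6)
  expect_equal(fit$loglik, 400 * log(fit$params$emission[1, 1]),
               tolerance = 1e-6)
})

test_that("training recovers well-separated emissions and the segmentation", {
  em_true <- default_emissions()
  trans <- phastcons_transition()
  truth_params <- hmm_params(trans, em_true)
  sim <- simulate_hmm(truth_params, nsim = 1, seed = 300, n_sites = 16569)[[1]]
  fit <- mitopopcons(as.integer(sim), transition = trans, seed = 301L)
  # match trained states to truth by monomorphic emission probability
  em <- fit$params$emission
  ord <- order(-em[, 1])
  tv <- rowSums(abs(em[ord, ] - em_true)) / 2
  expect_lt(tv[1], 0.05)
  expect_lt(tv[2], 0.05)
  # base-level F1 of the Viterbi segmentation against the true path
  true_f <- attr(sim, "states") == 1L
  called_f <- fit$path == fit$functional_state
  tp <- sum(true_f & called_f)
  prec <- tp / sum(called_f); rec <- tp / sum(true_f)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.9)
})

test_that("state labels are a relabeling symmetry, not a fit property", {
  cfg <- synthetic_config(genome_length = 4000L, n_samples = 1000L, seed = 81L,
                          control_length = 300L, origin_h = 50L,
                          origin_l = 2200L)
  lay <- generate_layout(cfg)
  st <- simulate_site_alleles(cfg, lay$truth)
  f1 <- mitopopcons(st, n_restarts = 3L, seed = 5L)
  f2 <- mitopopcons(st, n_restarts = 3L, seed = 1005L)
  # different restart initializations, same called elements after labeling
  expect_equal(f1$elements$start, f2$elements$start)
  expect_equal(f1$elements$end, f2$elements$end)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
})

test_that("element calling extracts maximal functional runs", {
  es <- call_elements(c(1L, 1L, 2L, 2L, 2L, 1L), functional_state = 2L)
  expect_equal(es$start, 2L)
  expect_equal(es$end, 5L)
  expect_equal(nrow(call_elements(rep(1L, 10), 2L)), 0L)
  path <- sample(1:2, 500, TRUE)
  es2 <- call_elements(path, 2L)
  gaps <- call_elements(path, 1L)
  expect_equal(sum(es2$end - es2$start) + sum(gaps$end - gaps$start), 500L)
})

test_that("the model object supports the standard S3 interface", {
  em <- default_emissions()
  p <- hmm_params(phastcons_transition(), em)
  sim <- simulate_hmm(p, nsim = 2, seed = 17, n_sites = 2000)
  expect_length(sim, 2L)
  expect_false(identical(sim[[1]], sim[[2]]))
  fit <- mitopopcons(sim[[1]], n_restarts = 3L, seed = 19L)
  expect_output(print(fit), "functional state")
  expect_output(print(summary(fit)), "emission matrix")
  expect_named(coef(fit), c("emission", "transition", "initial"))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(predict(fit), fit$path)
  expect_equal(dim(predict(fit, type = "posterior")), c(2000L, 2L))
  expect_s3_class(predict(fit, type = "elements"), "element_set")
  # prediction on new data reuses trained parameters
  nd <- predict(fit, newdata = sim[[2]], type = "viterbi")
  expect_length(nd, 2000L)
  sims <- simulate(fit, nsim = 1, seed = 23)
  expect_true(all(sims[[1]] %in% 1:4))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("phastCons-style transition parametrization is honored", {
  tr <- phastcons_transition(expected_length = 100, coverage = 0.5)
  expect_equal(tr, rbind(c(0.99, 0.01), c(0.01, 0.99)))
  tr2 <- phastcons_transition(expected_length = 50, coverage = 0.2)
  expect_equal(tr2[1, 1], 1 - 1 / 50)
  expect_equal(tr2[2, 2], 1 - 1 / 200)
  expect_equal(stationary_distribution(tr2), c(0.2, 0.8), tolerance = 1e-12)
})
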