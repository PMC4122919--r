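#' @useDynLib mitopopcons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Two-state HMM parameters over distinct-allele counts
#'
#' @param transition 2x2 row-stochastic matrix (rows sum to 1 within 1e-12).
#' @param emission 2x4 row-stochastic matrix over the observations 1..4
#'   (number of distinct alleles at a site).
#' @param initial length-2 initial state distribution; default the
#'   stationary distribution of `transition`.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(transition, emission, initial = NULL) {
  transition <- as.matrix(transition); emission <- as.matrix(emission)
  check_stochastic(transition, "transition")
  check_stochastic(emission, "emission")
  if (nrow(transition) != nrow(emission))
    stop("transition and emission state counts differ")
  if (is.null(initial)) initial <- stationary_distribution(transition)
  initial <- as.numeric(initial)
  if (length(initial) != nrow(transition) || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-12)
    stop("initial must be a distribution over the states")
  structure(list(transition = unname(transition), emission = unname(emission),
                 initial = initial,
                 n_states = nrow(transition), n_symbols = ncol(emission)),
            class = "hmm_params")
}

check_stochastic <- function(m, what) {
  if (any(m < 0)) stop(what, " matrix has negative entries")
  if (any(abs(rowSums(m) - 1) > 1e-12)) stop(what, " matrix rows must sum to 1")
  invisible(m)
}

#' Stationary distribution of a row-stochastic matrix
#' @param transition square row-stochastic matrix.
#' @return numeric probability vector.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Fixed transition matrix in the conserved-element parametrization
#'
#' The transition structure of conserved-element HMMs is usually stated as
#' an expected element length and an expected genome coverage rather than
#' raw probabilities: the constrained state's expected run length is
#' `expected_length` bp (stay probability `1 - 1/expected_length`) and the
#' unconstrained state's expected run length is
#' `expected_length * (1 - coverage) / coverage`. With the defaults
#' (100 bp, coverage 0.5) this is a symmetric matrix with stay
#' probability 0.99 — the package default when none is supplied.
#'
#' @param expected_length expected constrained-element length in bp.
#' @param coverage expected fraction of the genome in the constrained state.
#' @return 2x2 row-stochastic matrix; state 1 = constrained by convention
#'   (but training relabels states by their trained emissions, so the
#'   convention is not load-bearing).
#' @export
phastcons_transition <- function(expected_length = 100, coverage = 0.5) {
  if (expected_length <= 1 || coverage <= 0 || coverage >= 1)
    stop("need expected_length > 1 and coverage in (0,1)")
  len_n <- expected_length * (1 - coverage) / coverage
  a_cc <- 1 - 1 / expected_length
  a_nn <- 1 - 1 / len_n
  matrix(c(a_cc, 1 - a_cc, 1 - a_nn, a_nn), 2, 2, byrow = TRUE)
}

check_obs <- function(observations, n_symbols = 4L) {
  observations <- as.integer(observations)
  if (!length(observations)) stop("observations must be non-empty")
  if (any(is.na(observations)) || any(observations < 1L) ||
      any(observations > n_symbols))
    stop("observations must lie in 1..", n_symbols)
  observations
}

#' Forward log-likelihood of an observation sequence
#'
#' Scaled forward recursion; no underflow at genome scale.
#'
#' @param params an [hmm_params].
#' @param observations integer vector with values in 1..4 (distinct-allele
#'   counts), or a [site_table].
#' @return log P(observations | params).
#' @export
forward_loglik <- function(params, observations) {
  stopifnot(inherits(params, "hmm_params"))
  if (inherits(observations, "site_table")) observations <- observations$allele_count
  obs <- check_obs(observations, params$n_symbols)
  .hmm_forward_cpp(obs, params$transition, params$emission, params$initial)
}

#' Viterbi decoding
#'
#' Maximum-probability state path; ties at each backtrack step are broken
#' toward the lower state index, so the path is deterministic.
#'
#' @inheritParams forward_loglik
#' @return list with `path` (integer states, 1-based) and `logprob` (log
#'   probability of the returned path).
#' @export
viterbi_decode <- function(params, observations) {
  stopifnot(inherits(params, "hmm_params"))
  if (inherits(observations, "site_table")) observations <- observations$allele_count
  obs <- check_obs(observations, params$n_symbols)
  v <- .hmm_viterbi_cpp(obs, params$transition, params$emission, params$initial)
  list(path = v$path + 1L, logprob = v$logprob)
}

#' Maximal runs of the functional state as called elements
#'
#' @param path integer state path (1-based states).
#' @param functional_state the state index whose runs are the constrained
#'   elements.
#' @param genome_length genome size (defaults to the path length).
#' @param source provenance tag for the resulting [element_set].
#' @return an [element_set] of half-open intervals.
#' @export
call_elements <- function(path, functional_state, genome_length = length(path),
                          source = "popcons_hmm") {
  if (length(path) != genome_length) stop("path length must equal genome_length")
  r <- rle(path == functional_state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  element_set(starts[keep], ends[keep], genome_length,
              label = "constrained", source = source)
}

#' Fit the polymorphism-based constrained-element HMM
#'
#' The core model of the package: a two-state (constrained vs
#' unconstrained) hidden Markov model whose per-site observation is the
#' number of distinct alleles (1..4) seen in a population sample. The
#' transition matrix is supplied and held fixed; only the emission matrix
#' is learned, by Baum-Welch EM in which the transition M-step is swamped
#' by pseudocounts (`pseudocount * transition`) so the transitions stay
#' within ~1e-6 of their fixed values. Each of `n_restarts` restarts draws
#' its initial emission rows from a symmetric Dirichlet (restart `r` is
#' seeded with `seed + r - 1`); the restart with the highest final
#' log-likelihood is kept. The state with the higher trained probability
#' of emitting monomorphic sites (observation 1) is labelled functional,
#' and the constrained elements are the maximal functional-state runs of
#' the Viterbi path.
#'
#' @param x a [site_table] or an integer vector of per-site distinct-allele
#'   counts in 1..4 (every genome position, monomorphic sites = 1).
#' @param transition fixed 2x2 row-stochastic transition matrix; default
#'   [phastcons_transition()] (symmetric, stay probability 0.99, i.e.
#'   100 bp expected run length). The initial distribution is its
#'   stationary distribution.
#' @param n_restarts number of random emission initializations (default 10).
#' @param seed integer seed for the restart initializations.
#' @param tol stop a restart when the log-likelihood gain falls below this
#'   (default 1e-6).
#' @param max_iter EM iteration cap per restart (default 500).
#' @param pseudocount transition pseudocount scale (default 1e9).
#' @param emission_floor lower bound applied to emission probabilities each
#'   M-step (default 1e-10) so no emission is exactly zero.
#' @return an object of class `mitopopcons`: the trained [hmm_params]
#'   (`params`), `loglik`, `functional_state`, per-restart log-likelihoods
#'   and iteration counts (`restarts`), the Viterbi `path`, posterior state
#'   probabilities (`posterior`), the called `elements`, the observations
#'   and the seed.
#' @seealso [predict.mitopopcons()], [simulate.mitopopcons()],
#'   [call_elements()], [phastcons_transition()]
#' @export
mitopopcons <- function(x, transition = phastcons_transition(),
                        n_restarts = 10L, seed = NULL, tol = 1e-6,
                        max_iter = 500L, pseudocount = 1e9,
                        emission_floor = 1e-10) {
  obs <- if (inherits(x, "site_table")) x$allele_count else as.integer(x)
  obs <- check_obs(obs)
  check_stochastic(transition <- as.matrix(transition), "transition")
  if (is.null(seed)) seed <- sample.int(1e6, 1L)
  seed <- as.integer(seed)
  init <- stationary_distribution(transition)

  restarts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    e0 <- matrix(stats::rgamma(8, shape = 1), 2, 4)
    e0 <- e0 / rowSums(e0)
    fit <- .hmm_baum_welch_cpp(obs, transition, e0, init, pseudocount,
                               tol, as.integer(max_iter), emission_floor)
    restarts[[r]] <- fit
  }
  lls <- vapply(restarts, `[[`, numeric(1), "loglik")
  best <- restarts[[which.max(lls)]]
  emission <- best$emission
  if (max(abs(emission[1, ] - emission[2, ])) < 1e-6)
    warning("trained emission rows are (near-)identical: states are not ",
            "identifiable on these observations")
  params <- hmm_params(best$transition, emission, init)
  functional_state <- which.max(emission[, 1])
  vit <- viterbi_decode(params, obs)
  fb <- .hmm_fwbw_cpp(obs, params$transition, params$emission, params$initial)
  elements <- call_elements(vit$path, functional_state, length(obs))
  structure(list(params = params,
                 loglik = best$loglik,
                 functional_state = functional_state,
                 restarts = list(loglik = lls,
                                 iterations = vapply(restarts, `[[`, integer(1), "iterations"),
                                 best = which.max(lls),
                                 loglik_trace = best$loglik_trace,
                                 traces = lapply(restarts, `[[`, "loglik_trace"),
                                 transition_drift = vapply(restarts, function(r)
                                   max(abs(r$transition - transition)), numeric(1))),
                 path = vit$path,
                 path_logprob = vit$logprob,
                 posterior = fb$gamma,
                 elements = elements,
                 observations = obs,
                 n = length(obs),
                 seed = seed,
                 fixed_transition = transition),
            class = "mitopopcons")
}

#' @export
print.mitopopcons <- function(x, ...) {
  cat("mitoPopCons two-state allele-count HMM\n")
  cat("  sites:", x$n, " log-likelihood:", sprintf("%.2f", x$loglik),
      sprintf("(best of %d restarts)\n", length(x$restarts$loglik)))
  cat("  functional state:", x$functional_state,
      sprintf("(P(monomorphic) = %.3f vs %.3f)\n",
              x$params$emission[x$functional_state, 1],
              x$params$emission[3 - x$functional_state, 1]))
  print(x$elements)
  invisible(x)
}

#' @export
summary.mitopopcons <- function(object, ...) {
  em <- object$params$emission
  dimnames(em) <- list(state = c("state1", "state2"), alleles = 1:4)
  w <- object$elements$end - object$elements$start
  out <- list(loglik = object$loglik,
              restart_logliks = object$restarts$loglik,
              emission = em,
              transition = object$params$transition,
              functional_state = object$functional_state,
              n_elements = nrow(object$elements),
              mean_element_length = if (length(w)) mean(w) else NA_real_,
              constrained_bp = sum(w),
              n = object$n)
  class(out) <- "summary.mitopopcons"
  out
}

#' @export
print.summary.mitopopcons <- function(x, ...) {
  cat("mitoPopCons fit over", x$n, "sites\n")
  cat("  log-likelihood", sprintf("%.2f", x$loglik), "; restarts:",
      paste(sprintf("%.1f", x$restart_logliks), collapse = ", "), "\n")
  cat("  emission matrix (rows = states, cols = allele count 1..4):\n")
  print(round(x$emission, 4))
  cat("  functional state:", x$functional_state, "\n")
  cat("  elements:", x$n_elements, "covering", x$constrained_bp, "bp",
      if (!is.na(x$mean_element_length))
        sprintf("(mean %.1f bp)", x$mean_element_length) else "", "\n")
  invisible(x)
}

#' @export
coef.mitopopcons <- function(object, ...) {
  list(emission = object$params$emission,
       transition = object$params$transition,
       initial = object$params$initial)
}

#' @export
logLik.mitopopcons <- function(object, ...) {
  # free parameters: emissions only (transitions fixed), 2 states x 3 df
  structure(object$loglik, df = 6L, nobs = object$n, class = "logLik")
}

#' Predictions from a fitted allele-count HMM
#'
#' @param object a [mitopopcons] fit.
#' @param newdata optional new observation vector or [site_table]; default
#'   the training observations (whose decodings are precomputed).
#' @param type `"viterbi"` (integer state path), `"posterior"` (T x 2
#'   matrix of posterior state probabilities), or `"elements"` (an
#'   [element_set] of functional-state Viterbi runs).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.mitopopcons <- function(object, newdata = NULL,
                                type = c("viterbi", "posterior", "elements"),
                                ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(switch(type, viterbi = object$path, posterior = object$posterior,
                  elements = object$elements))
  }
  obs <- if (inherits(newdata, "site_table")) newdata$allele_count
         else as.integer(newdata)
  obs <- check_obs(obs)
  switch(type,
    viterbi = viterbi_decode(object$params, obs)$path,
    posterior = .hmm_fwbw_cpp(obs, object$params$transition,
                              object$params$emission, object$params$initial)$gamma,
    elements = call_elements(viterbi_decode(object$params, obs)$path,
                             object$functional_state, length(obs)))
}

#' Simulate allele-count sequences from a fitted (or specified) HMM
#'
#' Draws hidden state paths from the Markov chain and observations from the
#' state emissions — the generative model the fit assumes.
#'
#' @param object a [mitopopcons] fit or an [hmm_params].
#' @param nsim number of sequences.
#' @param seed optional integer seed.
#' @param n_sites length of each simulated sequence (default: the training
#'   length for fits, required for bare parameter objects).
#' @param ... unused.
#' @return a list of `nsim` integer observation vectors, each carrying the
#'   hidden path in attribute `"states"`.
#' @export
simulate.mitopopcons <- function(object, nsim = 1, seed = NULL,
                                 n_sites = object$n, ...) {
  simulate_hmm(object$params, nsim, seed, n_sites)
}

#' @rdname simulate.mitopopcons
#' @export
simulate_hmm <- function(object, nsim = 1, seed = NULL, n_sites) {
  stopifnot(inherits(object, "hmm_params"))
  if (!is.null(seed)) set.seed(seed)
  K <- object$n_states; M <- object$n_symbols
  lapply(seq_len(nsim), function(s) {
    states <- integer(n_sites)
    states[1] <- sample.int(K, 1, prob = object$initial)
    for (t in seq_len(n_sites)[-1])
      states[t] <- sample.int(K, 1, prob = object$transition[states[t - 1], ])
    obs <- integer(n_sites)
    for (k in seq_len(K)) {
      idx <- which(states == k)
      if (length(idx))
        obs[idx] <- sample.int(M, length(idx), replace = TRUE,
                               prob = object$emission[k, ])
    }
    attr(obs, "states") <- states
    obs
  })
}

#' Plot a fitted allele-count HMM
#'
#' Posterior probability of the functional state along the genome, with
#' the called elements as a rug underneath and the observed polymorphic
#' sites above.
#'
#' @param x a [mitopopcons] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mitopopcons <- function(x, ...) {
  post <- x$posterior[, x$functional_state]
  graphics::plot(seq_len(x$n) - 1L, post, type = "l", ylim = c(-0.12, 1.12),
                 xlab = "genome position (bp)",
                 ylab = "P(constrained | data)", yaxt = "n", ...)
  graphics::axis(2, at = c(0, 0.5, 1))
  poly <- which(x$observations > 1L) - 1L
  if (length(poly))
    graphics::points(poly, rep(1.08, length(poly)), pch = "|", cex = 0.3,
                     col = "grey50")
  if (nrow(x$elements))
    graphics::rect(x$elements$start, -0.1, x$elements$end, -0.02,
                   col = "steelblue", border = NA)
  invisible(x)
}
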