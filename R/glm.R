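#' Poisson regression of per-site allele counts on a mutation-rate covariate
#'
#' Fits `counts ~ covariate` with a log link by iteratively reweighted least
#' squares, treating the number of segregating alleles at each site as a
#' Poisson response and the single-strandedness duration D_ssH as the
#' predictor. The residuals of this fit are the bias-corrected polymorphism
#' signal used by the partial-correlation analyses.
#'
#' Iteration stops when the relative deviance change falls below `tol`
#' (default 1e-8) or after `max_iter` iterations (default 100, an error).
#' A constant covariate yields an intercept-only fit with a warning (the
#' slope is `NA`). Standard errors come from the Fisher information at the
#' optimum.
#'
#' @param counts non-negative integer response (allele counts are >= 1, but
#'   any Poisson-supported response is accepted).
#' @param covariate numeric predictor, same length, finite.
#' @param residual_type `"deviance"` (default), `"pearson"` or `"response"`.
#' @param tol relative-deviance convergence tolerance.
#' @param max_iter iteration cap.
#' @return an object of class `poisson_glm`: coefficients (`intercept`,
#'   `slope`), `se`, `fitted`, `residuals`, `residual_type`, `iterations`,
#'   `deviance_trace` (deviance after each IRLS step), `deviance`,
#'   `converged`, `n`.
#' @export
fit_poisson_glm <- function(counts, covariate,
                            residual_type = c("deviance", "pearson", "response"),
                            tol = 1e-8, max_iter = 100L) {
  residual_type <- match.arg(residual_type)
  y <- as.numeric(counts)
  x <- as.numeric(covariate)
  if (length(y) != length(x)) stop("counts and covariate lengths differ")
  if (any(!is.finite(x))) stop("covariate must be finite")
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y)))
    stop("counts must be non-negative integers")
  n <- length(y)
  intercept_only <- stats::var(x) == 0
  if (intercept_only)
    warning("constant covariate: slope undefined, fitting intercept only")
  X <- if (intercept_only) cbind(1, deparse.level = 0)[rep(1, n), , drop = FALSE]
       else cbind(1, x)

  dev_fun <- function(mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    2 * sum(t1 - (y - mu))
  }
  beta <- c(log(max(mean(y), 1e-8)), numeric(ncol(X) - 1L))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  dev <- dev_fun(mu)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu
    z <- eta + (y - mu) / mu
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X, XtW %*% z))
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    dev_new <- dev_fun(mu)
    trace <- c(trace, dev_new)
    if (abs(dev_new - dev) / (abs(dev) + 0.1) < tol) {
      dev <- dev_new; converged <- TRUE; break
    }
    dev <- dev_new
  }
  if (!converged)
    stop("IRLS failed to converge in ", max_iter,
         " iterations; deviance trace: ",
         paste(sprintf("%.6g", utils::tail(trace, 5)), collapse = ", "))
  beta <- unname(beta)
  fisher <- t(X * mu) %*% X
  se <- unname(sqrt(diag(solve(fisher))))
  res <- switch(residual_type,
    deviance = {
      di <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      sign(y - mu) * sqrt(pmax(di, 0))
    },
    pearson = (y - mu) / sqrt(mu),
    response = y - mu)
  coefs <- if (intercept_only) c(intercept = beta[1], slope = NA_real_)
           else c(intercept = beta[1], slope = beta[2])
  ses <- if (intercept_only) c(intercept = se[1], slope = NA_real_)
         else c(intercept = se[1], slope = se[2])
  structure(list(coefficients = coefs, se = ses, fitted = mu,
                 residuals = res, residual_type = residual_type,
                 iterations = length(trace), deviance_trace = trace,
                 deviance = dev, converged = converged, n = n),
            class = "poisson_glm")
}

#' @export
print.poisson_glm <- function(x, ...) {
  cat("Poisson GLM (log link), n =", x$n, "\n")
  cat(sprintf("  intercept %.6g (se %.3g)", x$coefficients[1], x$se[1]))
  if (!is.na(x$coefficients[2]))
    cat(sprintf(", slope %.6g (se %.3g)", x$coefficients[2], x$se[2]))
  cat("\n  deviance", sprintf("%.6g", x$deviance), "after", x$iterations,
      "IRLS iterations;", x$residual_type, "residuals\n")
  invisible(x)
}

#' @export
coef.poisson_glm <- function(object, ...) object$coefficients

#' @export
residuals.poisson_glm <- function(object, ...) object$residuals

#' @export
fitted.poisson_glm <- function(object, ...) object$fitted

#' Partial correlation of bias-corrected polymorphism with divergence
#'
#' Spearman correlation between the residuals of a [fit_poisson_glm()] fit
#' (polymorphism with the replication-bias covariate removed) and a
#' divergence score vector aligned to the same sites.
#'
#' @param fit a fit from [fit_poisson_glm()].
#' @param scores numeric vector of divergence scores for the fitted sites
#'   (same length and order as the fit's response).
#' @return a correlation result (see [spearman_cor()]); `rho` is `NA` with a warning when the
#'   residuals are constant.
#' @export
residual_partial_correlation <- function(fit, scores) {
  stopifnot(inherits(fit, "poisson_glm"))
  if (length(scores) != fit$n)
    stop("scores length does not match the number of fitted sites")
  spearman_cor(residuals(fit), scores)
}
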