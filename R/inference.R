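# Maximum-likelihood estimation of founder switch rates and their
# conversion to stationary admixture proportions.

#' Stationary admixture proportions implied by switch rates
#'
#' For founder j, the long-run fraction of sites with population-A
#' ancestry is `m0_j = rateBA_j / (rateAB_j + rateBA_j)`;
#' `m1_j = 1 - m0_j`. By the invariance principle of ML, proportions
#' computed from ML rate estimates are themselves ML estimates.
#'
#' @param model a [founder_model()].
#' @return Numeric vector `m0` of length `2^K`.
#' @export
rates_to_proportions <- function(model) {
  model$rateBA / (model$rateAB + model$rateBA)
}

#' Optimizer options for [fit_ml()]
#'
#' @param restarts number of random multi-starts (the likelihood is
#'   multimodal under pedigree-half relabeling).
#' @param maxit maximum quasi-Newton iterations per start.
#' @param reltol relative log-likelihood improvement declaring
#'   convergence.
#' @param pgtol projected-gradient norm declaring convergence.
#' @param rate_lo,rate_hi box for the per-bp switch rates. The
#'   expected ancestry-switch rate is of order g*rho ~ 1e-7 per bp for
#'   typical recent admixture, so the default box spans +-3 orders of
#'   magnitude around it.
#' @param fd_step central finite-difference step on the transformed
#'   scale.
#' @param seed integer seed for the random starts (`NULL`: leave the
#'   RNG state alone).
#' @return List of options.
#' @export
fit_options <- function(restarts = 3L, maxit = 500L, reltol = 1e-7,
                        pgtol = 1e-5, rate_lo = 1e-10, rate_hi = 1e-4,
                        fd_step = 1e-4, seed = NULL) {
  stopifnot(restarts >= 1L, rate_lo > 0, rate_hi > rate_lo)
  list(restarts = as.integer(restarts), maxit = as.integer(maxit),
       reltol = reltol, pgtol = pgtol, rate_lo = rate_lo,
       rate_hi = rate_hi, fd_step = fd_step, seed = seed)
}

# Logit transform of the log-position of a rate inside the box
# [rate_lo, rate_hi]; rates vary over orders of magnitude, so the
# bounded parameter fed to the optimizer is log-scaled.
rate_to_theta <- function(rate, lo, hi) {
  u <- (log(rate) - log(lo)) / (log(hi) - log(lo))
  qlogis(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

theta_to_rate <- function(theta, lo, hi) {
  pmin(pmax(exp(log(lo) + (log(hi) - log(lo)) * plogis(theta)), lo), hi)
}

#' Maximum-likelihood fit of ancestor admixture proportions
#'
#' Maximizes the forward log-likelihood over the `2^(K+1)` per-founder
#' switch rates with L-BFGS on logit-transformed, box-bounded rates,
#' using central finite-difference gradients and random multi-starts.
#' The phase-switch rate `pp` is a known input, not a free parameter.
#'
#' @param genome a [phased_genome()].
#' @param sites a [site_table()] (already preprocessed/pruned).
#' @inheritParams ac_bits
#' @param pp known per-bp phase-switch error rate.
#' @param options a [fit_options()] list.
#' @return Object of class `"fit_result"`: list with `model_hat`,
#'   `m0_hat` (population-A proportion per founder, left to right),
#'   `loglik`, `n_evals`, `converged`, `restarts` (per-start summary),
#'   `K`, `trace` (objective values of the best start, in evaluation
#'   order).
#' @export
fit_ml <- function(genome, sites, K, pp = 0, options = fit_options()) {
  K <- check_K(K)
  if (all(abs(sites$freqA - sites$freqB) < sqrt(.Machine$double.eps))) {
    stop("degenerate data: no site distinguishes populations A and B")
  }
  lo <- options$rate_lo; hi <- options$rate_hi
  npar <- 2L * 2L^K
  nC <- 2L^K

  n_evals <- 0L
  trace <- NULL
  negll <- function(theta) {
    r <- theta_to_rate(theta, lo, hi)
    model <- founder_model(K, r[seq_len(nC)], r[nC + seq_len(nC)],
                           pp = pp, rate_cap = hi)
    ll <- loglikelihood(genome, sites, model)
    n_evals <<- n_evals + 1L
    if (!is.finite(ll)) return(1e10)
    trace <<- c(trace, ll)
    -ll
  }
  grad <- function(theta) {
    h <- options$fd_step
    vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (negll(tp) - negll(tm)) / (2 * h)
    }, numeric(1))
  }

  if (!is.null(options$seed)) set.seed(options$seed)
  # Start 1: jittered centered start (m0 near 0.5, total switch rate of
  # order g*rho). The exactly symmetric point is a fixed point of the
  # gradient flow (founders exchangeable), so it is always jittered.
  center <- rate_to_theta(rep(1e-7, npar), lo, hi)
  starts <- c(list(center + rnorm(npar, 0, 0.5)),
              lapply(seq_len(options$restarts - 1L), function(s) {
                m0 <- runif(nC, 0.1, 0.9)
                tot <- exp(runif(nC, log(lo * 2), log(hi)))
                rateBA <- pmin(pmax(m0 * tot, lo), hi)
                rateAB <- pmin(pmax((1 - m0) * tot, lo), hi)
                rate_to_theta(c(rateAB, rateBA), lo, hi)
              }))

  # The transformed parameters are additionally boxed to [-12, 12]:
  # beyond that the logit saturates and finite-difference gradients
  # vanish, freezing the parameter at the box edge.
  results <- lapply(starts, function(theta0) {
    trace <<- NULL
    res <- optim(pmin(pmax(theta0, -11), 11), fn = negll, gr = grad,
                 method = "L-BFGS-B",
                 lower = rep(-12, npar), upper = rep(12, npar),
                 control = list(maxit = options$maxit,
                                factr = options$reltol / .Machine$double.eps,
                                pgtol = options$pgtol))
    list(par = res$par, loglik = -res$value,
         converged = res$convergence == 0L, trace = trace)
  })

  lls <- vapply(results, `[[`, numeric(1), "loglik")
  best <- results[[which.max(lls)]]
  r <- theta_to_rate(best$par, lo, hi)
  model_hat <- founder_model(K, r[seq_len(nC)], r[nC + seq_len(nC)],
                             pp = pp, rate_cap = hi)
  structure(list(
    model_hat = model_hat,
    m0_hat = rates_to_proportions(model_hat),
    loglik = best$loglik,
    n_evals = n_evals,
    converged = best$converged,
    restarts = lapply(results, function(x) {
      rr <- theta_to_rate(x$par, lo, hi)
      list(loglik = x$loglik, converged = x$converged,
           rateAB = rr[seq_len(nC)], rateBA = rr[nC + seq_len(nC)])
    }),
    K = K,
    trace = best$trace
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> K = %d, loglik = %.3f (%s, %d evaluations)\n",
              x$K, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_evals))
  cat("  m0_hat (population A):",
      paste(sprintf("%.3f", x$m0_hat), collapse = " "), "\n")
  invisible(x)
}
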