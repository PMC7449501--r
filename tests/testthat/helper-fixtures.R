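# Shared fixtures: random models/site tables, and independent oracles
# (dense transition matrices built entry-by-entry from transition_prob,
# brute-force path enumeration) used to validate the d&c forward pass.

random_model <- function(K, pp = 2e-5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founder_model(K, runif(2^K, 1e-8, 5e-4), runif(2^K, 1e-8, 5e-4),
                pp = pp, rate_cap = 1e-2)
}

random_sites <- function(n, chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  site_table(chrom, cumsum(sample(100:2000, n, replace = TRUE)),
             freqA = runif(n), freqB = runif(n),
             rec_prob = c(NA, runif(n - 1, 0, 0.3)))
}

random_genome <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phased_genome(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
}

# Dense transition matrix assembled entry-by-entry from the scalar
# transition_prob() -- independent of the d&c code path.
dense_T_oracle <- function(d, rec_prob, model) {
  N <- n_states(model$K)
  outer(0:(N - 1L), 0:(N - 1L),
        Vectorize(function(to, from) {
          transition_prob(from, to, d, rec_prob, model)
        }))
}

# One dense row (fixed `to`, all `from`) computed bit-by-bit in plain
# R: independent oracle cheap enough for K = 3.
dense_row_oracle <- function(to, d, rec_prob, model,
                             cap = 0.5) {
  K <- model$K
  b <- ac_bits(K)
  N <- n_states(K)
  from <- 0:(N - 1L)
  t01 <- c(min(d * model$pp, cap), pmin(d * model$rateAB, cap),
           rep(rec_prob, 2^K - 2))
  t10 <- c(min(d * model$pp, cap), pmin(d * model$rateBA, cap),
           rep(rec_prob, 2^K - 2))
  row <- rep(1, N)
  for (k in seq_len(b)) {
    shift <- b - k
    xf <- bitwAnd(bitwShiftR(from, shift), 1L)
    xt <- bitwAnd(bitwShiftR(as.integer(to), shift), 1L)
    row <- row * ifelse(xf == 0L,
                        if (xt == 1L) t01[k] else 1 - t01[k],
                        if (xt == 0L) t10[k] else 1 - t10[k])
  }
  row
}

# Exhaustive path-enumeration likelihood (vectorized over all N^n
# hidden paths). Tractable for K=1 n<=6 and K=2 n<=3.
enumeration_loglik <- function(genome, sites, model) {
  K <- model$K
  N <- n_states(K)
  n <- nrow(sites)
  init <- init_distribution(model)
  Tm <- lapply(seq_len(n)[-1L], function(i) {
    dense_T_oracle(sites$gap_bp[i], sites$rec_prob[i], model)
  })
  em <- vapply(0:(N - 1L), function(s) {
    vapply(seq_len(n), function(i) {
      emission_prob(s, c(genome$h1[i], genome$h2[i]),
                    sites$freqA[i], sites$freqB[i], K)
    }, numeric(1))
  }, numeric(n))                         # n x N
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  p <- init[paths[, 1L]] * em[cbind(1L, paths[, 1L])]
  for (i in seq_len(n)[-1L]) {
    p <- p * Tm[[i - 1L]][cbind(paths[, i], paths[, i - 1L])] *
      em[cbind(i, paths[, i])]
  }
  log(sum(p))
}

# Small admixture simulation used across tests (fast: ~2 s).
tiny_sim <- function(seed, g = 10L, n_i = 2L, admix_frac = 0.5,
                     pp = 0, t = 0.2, L = 2e7, n_c = 3L, n_h = 100L) {
  simulate_admixture(sim_config(n_h = n_h, n_c = n_c, L = L, g = g,
                                t = t, n_i = n_i, pp = pp,
                                admix_frac = admix_frac, seed = seed))
}

# Pedigree-half swap of a founder model: founders of the left and
# right halves exchanged (with their rates). For the matching state
# relabeling the likelihood is invariant.
swap_halves <- function(model) {
  nC <- 2L^model$K
  perm <- c((nC / 2 + 1):nC, 1:(nC / 2))
  founder_model(model$K, model$rateAB[perm], model$rateBA[perm],
                pp = model$pp, rate_cap = 1e-2)
}
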