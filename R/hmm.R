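# Transition/emission model and the forward likelihood.
#
# Per-bit one-step probabilities are linear in the bp gap d (switch
# probability d * rate), with the switch probability clamped at
# `switch_cap` (default 0.5, the maximal informative value for a
# binary chain): after pruning, gaps can grow large enough that the
# linear approximation would exceed 1.

.default_switch_cap <- 0.5

#' Ancestry one-step transition probability of one founder bit
#'
#' Probability that a founder's population-of-origin bit moves from
#' `prev_bit` to `cur_bit` across a gap of `d` bp, with per-bp switch
#' rates `rateAB` (A to B) and `rateBA` (B to A). The switch
#' probability is `d * rate` clamped at `switch_cap`; stay and switch
#' always sum to 1.
#'
#' @param prev_bit,cur_bit ancestry bits (0 = population A, 1 = B).
#' @param d gap in bp (non-negative).
#' @param rateAB,rateBA per-bp switch rates.
#' @param switch_cap clamp for the switch probability.
#' @return Transition probability.
#' @export
ancestry_step_prob <- function(prev_bit, cur_bit, d, rateAB, rateBA,
                               switch_cap = .default_switch_cap) {
  if (any(d < 0)) stop("d must be non-negative")
  sw <- ifelse(prev_bit == 0, pmin(d * rateAB, switch_cap),
               pmin(d * rateBA, switch_cap))
  ifelse(cur_bit == prev_bit, 1 - sw, sw)
}

#' Phase-switch one-step transition probability
#'
#' As [ancestry_step_prob()] with the single phase-switch rate `pp`.
#'
#' @param prev_P,cur_P phase bits.
#' @param d gap in bp.
#' @param pp per-bp phase-switch rate.
#' @inheritParams ancestry_step_prob
#' @export
phase_step_prob <- function(prev_P, cur_P, d, pp,
                            switch_cap = .default_switch_cap) {
  if (any(d < 0)) stop("d must be non-negative")
  sw <- pmin(d * pp, switch_cap)
  ifelse(cur_P == prev_P, 1 - sw, sw)
}

#' Recombination-arrow one-step transition probability
#'
#' Every recombination bit flips with the inter-site recombination
#' probability and stays with its complement.
#'
#' @param prev_bit,cur_bit arrow bits.
#' @param rec_prob probability of at least one crossover between the
#'   two sites, in `[0, 0.5]`.
#' @export
recomb_step_prob <- function(prev_bit, cur_bit, rec_prob) {
  if (any(rec_prob < 0 | rec_prob > 0.5)) stop("rec_prob must be in [0, 0.5]")
  ifelse(cur_bit == prev_bit, 1 - rec_prob, rec_prob)
}

#' Full AC-to-AC transition probability
#'
#' Product of the independent per-bit transitions: the phase bit, all
#' recombination bits, and each founder's ancestry bit (using that
#' founder's switch rates).
#'
#' @param ac_from,ac_to packed state indices.
#' @param d gap in bp.
#' @param rec_prob inter-site recombination probability.
#' @param model a [founder_model()].
#' @inheritParams ancestry_step_prob
#' @export
transition_prob <- function(ac_from, ac_to, d, rec_prob, model,
                            switch_cap = .default_switch_cap) {
  K <- model$K
  from <- decode_ac(ac_from, K)
  to <- decode_ac(ac_to, K)
  p <- phase_step_prob(from$P, to$P, d, model$pp, switch_cap)
  for (j in seq_along(from$C)) {
    p <- p * ancestry_step_prob(from$C[j], to$C[j], d,
                                model$rateAB[j], model$rateBA[j], switch_cap)
  }
  for (k in seq_along(from$R)) {
    p <- p * recomb_step_prob(from$R[k], to$R[k], rec_prob)
  }
  p
}

# One row of the dense transition matrix: p_t(to | from) for a fixed
# `to` over all N `from` states, computed independently of the d&c
# path (vectorized per-bit products). Oracle for tests; also the
# building block for transition_matrix().
dense_transition_row <- function(ac_to, d, rec_prob, model,
                                 switch_cap = .default_switch_cap) {
  K <- model$K
  b <- ac_bits(K)
  N <- n_states(K)
  from <- 0:(N - 1L)
  t01 <- c(pmin(d * model$pp, switch_cap),
           pmin(d * model$rateAB, switch_cap),
           rep(rec_prob, 2L^K - 2L))
  t10 <- c(pmin(d * model$pp, switch_cap),
           pmin(d * model$rateBA, switch_cap),
           rep(rec_prob, 2L^K - 2L))
  row <- rep(1, N)
  for (k in seq_len(b)) {            # k-th bit from the MSB
    shift <- b - k
    xf <- bitwAnd(bitwShiftR(from, shift), 1L)
    xt <- bitwAnd(bitwShiftR(as.integer(ac_to), shift), 1L)
    f <- if (xt == 1L) ifelse(xf == 0L, t01[k], 1 - t10[k])
         else          ifelse(xf == 0L, 1 - t01[k], t10[k])
    row <- row * f
  }
  row
}

#' Dense AC transition matrix
#'
#' Materializes `T[to, from] = p_t(to | from)`. Quadratic in the state
#' count; intended for small `K` and for validating the
#' divide-and-conquer product.
#'
#' @inheritParams transition_prob
#' @export
transition_matrix <- function(d, rec_prob, model,
                              switch_cap = .default_switch_cap) {
  N <- n_states(model$K)
  if (N > 1024L) stop("dense transition matrix only supported for K <= 2")
  t(vapply(0:(N - 1L), dense_transition_row, numeric(N),
           d = d, rec_prob = rec_prob, model = model,
           switch_cap = switch_cap))
}

#' Emission probability of the observed allele pair
#'
#' Each haplotype is traced through the phase and recombination arrows
#' to a founder; the emission is the product over the two haplotypes
#' of the frequency of the observed allele in that founder's current
#' population (freq for allele 1, 1 - freq for allele 0).
#'
#' @param ac packed state index.
#' @param alleles length-2 vector `(h1, h2)` of observed alleles.
#' @param freqA,freqB frequency of allele "1" in populations A and B.
#' @inheritParams ac_bits
#' @export
emission_prob <- function(ac, alleles, freqA, freqB, K) {
  if (any(c(freqA, freqB) < 0 | c(freqA, freqB) > 1)) {
    stop("frequencies must be in [0, 1]")
  }
  st <- decode_ac(ac, K)
  p <- 1
  for (j in 1:2) {
    f_idx <- founder_of(j, st$P, st$R, K)
    pop <- st$C[f_idx]
    f1 <- if (pop == 0L) freqA else freqB    # freq of allele "1"
    a <- alleles[j]
    p <- p * if (a == 1) f1 else 1 - f1
  }
  p
}

#' Initial distribution of the AC chain
#'
#' Phase and recombination bits uniform; each founder's ancestry bit
#' at its stationary law `P(C_j = 0) = m0_j`.
#'
#' @param model a [founder_model()].
#' @return Probability vector of length `n_states(model$K)`.
#' @export
init_distribution <- function(model) {
  K <- model$K
  m0 <- rates_to_proportions(model)
  b <- ac_bits(K)
  p0 <- c(0.5, m0, rep(0.5, 2L^K - 2L))   # MSB-first per-bit P(bit = 0)
  v <- 1
  for (k in seq_len(b)) v <- rep(v, each = 2L) * c(p0[k], 1 - p0[k])
  v
}

#' One divide-and-conquer forward step
#'
#' Computes the transition-matrix/vector product `T %*% prev_probs`
#' exactly (up to roundoff) by peeling one bit per recursion level,
#' in `O(N log N)` scalar multiply-adds.
#'
#' @param prev_probs non-negative state-probability vector of length
#'   `n_states(model$K)`.
#' @inheritParams transition_prob
#' @export
forward_step_dc <- function(prev_probs, d, rec_prob, model,
                            switch_cap = .default_switch_cap) {
  N <- n_states(model$K)
  if (length(prev_probs) != N) stop("prev_probs has wrong length")
  dc_forward_step_cpp(prev_probs, d, rec_prob, model$rateAB, model$rateBA,
                      model$pp, switch_cap)
}

# Pure-R instrumented d&c step: returns the result plus the number of
# scalar multiply-adds spent, for the complexity property test.
dc_step_counted <- function(prev_probs, t01, t10) {
  v <- prev_probs
  b <- length(t01)
  N <- length(v)
  ops <- 0
  for (k in seq_len(b)) {
    stride <- N %/% 2L^k
    dim(v) <- c(stride, 2L, N %/% (2L * stride))
    x0 <- v[, 1L, , drop = FALSE]
    x1 <- v[, 2L, , drop = FALSE]
    v[, 1L, ] <- (1 - t01[k]) * x0 + t10[k] * x1
    v[, 2L, ] <- t01[k] * x0 + (1 - t10[k]) * x1
    ops <- ops + 4L * length(x0)     # 4 multiplies (+2 adds) per pair
    v <- as.vector(v)
  }
  list(probs = v, multiply_adds = ops)
}

#' Log-likelihood of a phased genome under a founder model
#'
#' Runs the scaled forward algorithm over the AC state space, one
#' independent chain per chromosome, and returns the summed
#' log-likelihood. Each site multiplies in the emission and rescales
#' the state vector, accumulating the log normalizers.
#'
#' @param genome a [phased_genome()] aligned to `sites`.
#' @param sites a [site_table()].
#' @param model a [founder_model()].
#' @inheritParams ancestry_step_prob
#' @return Log-likelihood (scalar). `-Inf` if the data are impossible
#'   under the model (e.g. zero-probability emissions everywhere at
#'   some site).
#' @export
loglikelihood <- function(genome, sites, model,
                          switch_cap = .default_switch_cap) {
  n <- nrow(sites)
  if (n == 0L) stop("site table is empty")
  if (length(genome$h1) != n) {
    stop("genome and site table have different numbers of sites")
  }
  if (any(!is.finite(sites$freqA)) || any(!is.finite(sites$freqB))) {
    stop("non-finite allele frequencies")
  }
  route <- founder_route_table(model$K)
  init <- init_distribution(model)
  total <- 0
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    gap <- sites$gap_bp[idx]
    recp <- sites$rec_prob[idx]
    gap[1L] <- 0; recp[1L] <- 0
    if (anyNA(gap) || anyNA(recp)) {
      stop("interior sites must have gap_bp and rec_prob defined")
    }
    total <- total + forward_loglik_chrom_cpp(
      genome$h1[idx], genome$h2[idx], gap, recp,
      sites$freqA[idx], sites$freqB[idx],
      model$rateAB, model$rateBA, model$pp, switch_cap, init,
      route$h1, route$h2)
  }
  total
}
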