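# Accuracy metrics: best-match mean absolute error and a random-guess
# baseline.
#
# Estimated ancestors are unlabeled up to sibling swaps at every
# internal node of the pedigree, so errors are always reported after
# minimizing over the 2^(2^K - 1) pedigree-consistent rotations
# (2 for parents, 8 for grandparents, 128 for great-grandparents).

#' Pedigree-consistent ancestor orderings
#'
#' @inheritParams ac_bits
#' @return List of permutation vectors of `1..2^K`, one per rotation
#'   (sibling swap at each internal node); length `2^(2^K - 1)`.
#' @export
pedigree_matchings <- function(K) {
  check_K(K)
  rotate <- function(leaves) {
    if (length(leaves) == 1L) return(list(leaves))
    half <- length(leaves) / 2L
    L <- rotate(leaves[seq_len(half)])
    R <- rotate(leaves[half + seq_len(half)])
    out <- list()
    for (l in L) for (r in R) {
      out[[length(out) + 1L]] <- c(l, r)
      out[[length(out) + 1L]] <- c(r, l)
    }
    out
  }
  rotate(seq_len(2L^K))
}

#' Best-match error between true and estimated ancestor proportions
#'
#' Enumerates all pedigree-consistent rotations of the estimated
#' ancestors and returns the minimal mean absolute error and the
#' permutation achieving it (ties broken by enumeration order).
#'
#' @param truth,est numeric vectors of length `2^K`: population-A
#'   proportions of the ancestors, left to right.
#' @inheritParams ac_bits
#' @return List with `error` (mean absolute error at the best
#'   matching), `matching` (permutation applied to `est`) and
#'   `per_ancestor` (absolute errors under that matching).
#' @export
best_match_error <- function(truth, est, K) {
  K <- check_K(K)
  nA <- 2L^K
  if (length(truth) != nA || length(est) != nA) {
    stop(sprintf("truth and est must each have %d proportions", nA))
  }
  best <- NULL
  for (perm in pedigree_matchings(K)) {
    err <- mean(abs(est[perm] - truth))
    if (is.null(best) || err < best$error - 1e-15) {
      best <- list(error = err, matching = perm,
                   per_ancestor = abs(est[perm] - truth))
    }
  }
  best
}

#' Mean best-match error over individuals
#'
#' The mean absolute error over all `n * 2^K` ancestor proportions,
#' with the matching chosen per individual. Only population-A
#' proportions are scored; with two populations the expected errors
#' for A and B are identical.
#'
#' @param truth_list,est_list lists of length-`2^K` proportion vectors,
#'   one per individual.
#' @inheritParams ac_bits
#' @return List of class `"error_report"`: `mean_error`, `per_individual`
#'   (matched error per individual), `matchings`, `K`.
#' @export
mean_error <- function(truth_list, est_list, K) {
  stopifnot(length(truth_list) == length(est_list),
            length(truth_list) >= 1L)
  per <- mapply(function(tr, es) best_match_error(tr, es, K),
                truth_list, est_list, SIMPLIFY = FALSE)
  structure(list(
    mean_error = mean(vapply(per, `[[`, numeric(1), "error")),
    per_individual = vapply(per, `[[`, numeric(1), "error"),
    matchings = lapply(per, `[[`, "matching"),
    K = check_K(K)), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> K = %d, mean error = %.4f over %d individuals\n",
              x$K, x$mean_error, length(x$per_individual)))
  invisible(x)
}

#' Random-guess baseline error
#'
#' Monte-Carlo expectation of the best-match error when each
#' ancestor's proportion is guessed by drawing from the empirical
#' distribution of individual proportions in the population. The
#' calibrated naive baseline that any informative method must beat.
#'
#' @param truth_list list of true ancestor-proportion vectors (length
#'   `2^K` each), one per individual.
#' @param pop_proportions numeric vector: empirical admixture
#'   proportions of individuals in the population to draw guesses
#'   from.
#' @inheritParams ac_bits
#' @param n_draws Monte-Carlo draws per individual.
#' @param seed optional seed.
#' @return Scalar expected mean error.
#' @export
random_guess_baseline <- function(truth_list, pop_proportions, K,
                                  n_draws = 200L, seed = NULL) {
  K <- check_K(K)
  if (!is.null(seed)) set.seed(seed)
  nA <- 2L^K
  errs <- vapply(truth_list, function(tr) {
    mean(vapply(seq_len(n_draws), function(i) {
      guess <- sample(pop_proportions, nA, replace = TRUE)
      best_match_error(tr, guess, K)$error
    }, numeric(1)))
  }, numeric(1))
  mean(errs)
}
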