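# Domain containers: SNP table, phased genome, founder model.

#' Build an ordered SNP site table
#'
#' Holds per-SNP metadata: position, allele frequencies of the
#' designated "1" allele in the two ancestral populations, and the
#' inter-site recombination probability. Recombination probabilities
#' are derived from the cumulative genetic-map position (`cM`) when
#' available: the probability of at least one crossover between
#' consecutive sites is the genetic distance in Morgans, clamped at
#' 0.5. Alternatively `rec_prob` can be supplied directly.
#'
#' @param chrom chromosome label per site.
#' @param pos_bp integer 1-based base-pair position, strictly
#'   increasing within each chromosome.
#' @param freqA,freqB frequency of the "1" allele in ancestral
#'   populations A and B, in `[0, 1]`.
#' @param cM cumulative genetic-map position in centimorgans
#'   (per chromosome), or `NULL`.
#' @param rec_prob inter-site recombination probability in `[0, 0.5]`
#'   (first site of each chromosome is `NA`), or `NULL` to derive it
#'   from `cM`.
#' @return A `data.frame` of class `"site_table"` with columns
#'   `chrom`, `pos_bp`, `freqA`, `freqB`, `cM`, `gap_bp`, `rec_prob`.
#' @export
site_table <- function(chrom, pos_bp, freqA, freqB, cM = NULL,
                       rec_prob = NULL) {
  n <- length(pos_bp)
  stopifnot(length(chrom) %in% c(1L, n), length(freqA) == n,
            length(freqB) == n)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (n == 0L) stop("site table must contain at least one site")
  if (any(!is.finite(freqA)) || any(!is.finite(freqB)) ||
      any(freqA < 0 | freqA > 1) || any(freqB < 0 | freqB > 1)) {
    stop("allele frequencies must be finite and in [0, 1]")
  }
  pos_bp <- as.numeric(pos_bp)
  new_chrom <- c(TRUE, chrom[-1L] != chrom[-n])
  gap <- c(NA_real_, diff(pos_bp))
  gap[new_chrom] <- NA_real_
  if (any(gap <= 0, na.rm = TRUE)) {
    stop("positions must be strictly increasing within each chromosome")
  }
  if (is.null(rec_prob)) {
    if (is.null(cM)) stop("supply either cM or rec_prob")
    stopifnot(length(cM) == n)
    rec_prob <- c(NA_real_, pmin(diff(cM) / 100, 0.5))
    rec_prob[new_chrom] <- NA_real_
    if (any(rec_prob < 0, na.rm = TRUE)) {
      stop("cumulative genetic positions must be non-decreasing")
    }
  } else {
    stopifnot(length(rec_prob) == n)
    rec_prob[new_chrom] <- NA_real_
    if (any(rec_prob < 0 | rec_prob > 0.5, na.rm = TRUE)) {
      stop("rec_prob must lie in [0, 0.5]")
    }
    if (is.null(cM)) cM <- rep(NA_real_, n)
  }
  out <- data.frame(chrom = as.character(chrom), pos_bp = pos_bp,
                    freqA = freqA, freqB = freqB, cM = cM,
                    gap_bp = gap, rec_prob = rec_prob,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_table", "data.frame")
  out
}

#' A phased diploid genome aligned to a site table
#'
#' @param h1,h2 binary haplotype vectors (entries 0/1) over the sites
#'   of the accompanying [site_table()].
#' @param sample_id sample label.
#' @return Object of class `"phased_genome"`: list with `h1`, `h2`
#'   (integer vectors) and `sample_id`.
#' @export
phased_genome <- function(h1, h2, sample_id = "sample") {
  if (length(h1) != length(h2)) stop("h1 and h2 must have equal length")
  h1 <- as.integer(h1); h2 <- as.integer(h2)
  if (anyNA(h1) || anyNA(h2) || !all(h1 %in% 0:1) || !all(h2 %in% 0:1)) {
    stop("haplotypes must be binary 0/1 vectors")
  }
  structure(list(h1 = h1, h2 = h2, sample_id = as.character(sample_id)),
            class = "phased_genome")
}

#' @export
print.phased_genome <- function(x, ...) {
  cat(sprintf("<phased_genome> %s: %d sites\n", x$sample_id, length(x$h1)))
  invisible(x)
}

#' Founder ancestry-switch model
#'
#' Per-founder ancestry switch rates of the generation-K founders'
#' Markov ancestry processes, plus the known per-bp phase-switch error
#' rate. The stationary proportion of founder j in population A is
#' `m0_j = rateBA_j / (rateAB_j + rateBA_j)`.
#'
#' @inheritParams ac_bits
#' @param rateAB,rateBA per-bp switch rates A->B and B->A for each of
#'   the `2^K` founders (left to right); each must be positive.
#' @param pp per-bp phase-switch error rate (known, held fixed during
#'   inference).
#' @param rate_cap upper bound accepted for the switch rates.
#' @return Object of class `"founder_model"`.
#' @export
founder_model <- function(K, rateAB, rateBA, pp = 0, rate_cap = 1e-2) {
  K <- check_K(K)
  nC <- 2L^K
  if (length(rateAB) == 1L) rateAB <- rep(rateAB, nC)
  if (length(rateBA) == 1L) rateBA <- rep(rateBA, nC)
  stopifnot(length(rateAB) == nC, length(rateBA) == nC)
  if (any(!is.finite(rateAB)) || any(!is.finite(rateBA)) ||
      any(rateAB <= 0) || any(rateBA <= 0) ||
      any(rateAB > rate_cap) || any(rateBA > rate_cap)) {
    stop(sprintf("switch rates must lie in (0, %g]", rate_cap))
  }
  if (length(pp) != 1L || !is.finite(pp) || pp < 0) {
    stop("pp must be a single non-negative rate")
  }
  structure(list(K = K, rateAB = as.numeric(rateAB),
                 rateBA = as.numeric(rateBA), pp = as.numeric(pp)),
            class = "founder_model")
}

#' @export
print.founder_model <- function(x, ...) {
  m0 <- rates_to_proportions(x)
  cat(sprintf("<founder_model> K = %d, pp = %g\n", x$K, x$pp))
  for (j in seq_along(m0)) {
    cat(sprintf("  founder %d: rateAB = %.3g, rateBA = %.3g, m0 = %.3f\n",
                j, x$rateAB[j], x$rateBA[j], m0[j]))
  }
  invisible(x)
}
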