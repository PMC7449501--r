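# Ancestral-configuration (AC) state space.
#
# A state at one SNP is the bit-triple (P, C, R):
#   P : 1 bit, the phase arrow (0 = H1 traces to the left half of the
#       pedigree, 1 = H1 traces to the right half);
#   C : 2^K bits, population of origin of each generation-K founder at
#       this site (0 = population A, 1 = population B), founders
#       numbered left to right;
#   R : 2^K - 2 bits, the recombination arrows of the meioses between
#       generations 1 and K, level by level (most recent level first),
#       left to right within a level (0 = left parent, 1 = right).
# Packed index layout: [P | C | R], most-significant bit first.

#' Number of bits of an ancestral configuration
#'
#' @param K target generation (1 = parents, 2 = grandparents,
#'   3 = great-grandparents).
#' @return Integer, `2^(K+1) - 1`.
#' @export
ac_bits <- function(K) {
  check_K(K)
  as.integer(2^(K + 1) - 1)
}

#' Size of the AC state space
#'
#' @inheritParams ac_bits
#' @return Integer `N_K = 2^(2^(K+1) - 1)`: 8 for K=1, 128 for K=2,
#'   32768 for K=3.
#' @export
n_states <- function(K) {
  bitwShiftL(1L, ac_bits(K))
}

check_K <- function(K) {
  if (length(K) != 1L || !is.finite(K) || K != as.integer(K) ||
      K < 1L || K > 3L) {
    stop("K must be 1 (parents), 2 (grandparents) or 3 (great-grandparents)",
         call. = FALSE)
  }
  invisible(as.integer(K))
}

#' Pack an ancestral configuration into its state index
#'
#' @param P phase bit (0 or 1).
#' @param C founder-ancestry bit vector of length `2^K` (0 = population
#'   A, 1 = population B), founders left to right.
#' @param R recombination bit vector of length `2^K - 2`.
#' @inheritParams ac_bits
#' @return Integer index in `[0, n_states(K))`.
#' @examples
#' encode_ac(1, c(0, 1, 0, 1), c(1, 0), K = 2)  # 86
#' @export
encode_ac <- function(P, C, R, K) {
  K <- check_K(K)
  nC <- 2L^K
  if (length(P) != 1L || !P %in% c(0, 1)) stop("P must be a single bit")
  if (length(C) != nC) {
    stop(sprintf("C must have %d bits for K = %d, got %d", nC, K, length(C)))
  }
  if (length(R) != nC - 2L) {
    stop(sprintf("R must have %d bits for K = %d, got %d",
                 nC - 2L, K, length(R)))
  }
  bits <- c(P, C, R)
  if (!all(bits %in% c(0, 1))) stop("AC bits must be 0 or 1")
  b <- length(bits)
  as.integer(sum(bits * 2^((b - 1L):0L)))
}

#' Unpack a state index into its (P, C, R) bits
#'
#' @param index integer state index in `[0, n_states(K))`.
#' @inheritParams ac_bits
#' @return List with elements `P` (bit), `C` (length `2^K`),
#'   `R` (length `2^K - 2`).
#' @export
decode_ac <- function(index, K) {
  K <- check_K(K)
  b <- ac_bits(K)
  if (length(index) != 1L || index < 0 || index >= 2^b) {
    stop(sprintf("index must lie in [0, %d)", 2L^b))
  }
  bits <- as.integer(bitwAnd(bitwShiftR(as.integer(index), (b - 1L):0L), 1L))
  nC <- 2L^K
  list(P = bits[1L], C = bits[1L + seq_len(nC)],
       R = if (nC > 2L) bits[(nC + 2L):b] else integer(0))
}

#' Founder reached by tracing a haplotype through the pedigree
#'
#' Traces the given haplotype through the phase arrow and the
#' recombination arrows down to a generation-K founder. The phase bit
#' sends H1 to the left half when `P = 0`; within a half, the R bit of
#' each meiosis picks the left (0) or right (1) child.
#'
#' @param hap which haplotype, 1 or 2.
#' @param P phase bit.
#' @param R recombination bit vector (length `2^K - 2`).
#' @inheritParams ac_bits
#' @return Founder index in `1..2^K` (numbered left to right).
#' @export
founder_of <- function(hap, P, R, K) {
  K <- check_K(K)
  nR <- 2L^K - 2L
  if (!hap %in% c(1, 2)) stop("hap must be 1 or 2")
  if (length(R) != nR) {
    stop(sprintf("R must have %d bits for K = %d", nR, K))
  }
  # 0-based node index within level 1 (the two pedigree halves)
  go_right <- if (hap == 1) P == 1 else P == 0
  cur <- as.integer(go_right)
  if (K > 1L) {
    for (lev in 2:K) {
      offset <- 2L^(lev - 1L) - 2L   # arrows in levels above this one
      bit <- R[offset + cur + 1L]
      cur <- 2L * cur + as.integer(bit)
    }
  }
  cur + 1L
}

# Lookup tables mapping each packed (P, R) combination to the founder
# indices fed by H1 and H2. pr = P * 2^nR + packed R bits (R[1] most
# significant). Used by the C++ forward pass.
founder_route_table <- function(K) {
  K <- check_K(K)
  nR <- 2L^K - 2L
  n_pr <- bitwShiftL(1L, 1L + nR)
  tab1 <- integer(n_pr)
  tab2 <- integer(n_pr)
  for (pr in 0:(n_pr - 1L)) {
    P <- bitwShiftR(pr, nR)
    R <- if (nR > 0L) {
      as.integer(bitwAnd(bitwShiftR(pr, (nR - 1L):0L), 1L))
    } else integer(0)
    tab1[pr + 1L] <- founder_of(1, P, R, K)
    tab2[pr + 1L] <- founder_of(2, P, R, K)
  }
  list(h1 = tab1, h2 = tab2)
}
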