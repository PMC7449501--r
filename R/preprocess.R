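# SNP pruning and phase-switch-error cleanup applied before inference.

subset_sites <- function(sites, keep) {
  site_table(chrom = sites$chrom[keep], pos_bp = sites$pos_bp[keep],
             freqA = sites$freqA[keep], freqB = sites$freqB[keep],
             cM = if (all(is.na(sites$cM))) NULL else sites$cM[keep],
             rec_prob = if (all(is.na(sites$cM))) {
               # no genetic map retained: combine interval rec_probs by
               # summing per-bp map mass across the gap, clamped at 0.5
               combine_rec_prob(sites, keep)
             } else NULL)
}

combine_rec_prob <- function(sites, keep) {
  keep <- sort(keep)
  out <- rep(NA_real_, length(keep))
  for (i in seq_along(keep)[-1L]) {
    a <- keep[i - 1L]; b <- keep[i]
    if (sites$chrom[a] != sites$chrom[b]) next
    span <- (a + 1L):b
    out[i] <- min(sum(sites$rec_prob[span]), 0.5)
  }
  out
}

subset_genome <- function(genome, keep) {
  phased_genome(genome$h1[keep], genome$h2[keep], genome$sample_id)
}

prune_report <- function(sites_before, sites_after, method, threshold) {
  structure(list(
    n_before = nrow(sites_before), n_after = nrow(sites_after),
    method = method, threshold = threshold,
    per_chromosome = list(
      before = as.list(table(sites_before$chrom)),
      after = as.list(table(sites_after$chrom)))),
    class = "prune_report")
}

#' @export
print.prune_report <- function(x, ...) {
  cat(sprintf("<prune_report> %s (threshold %g): %d -> %d sites\n",
              x$method, x$threshold, x$n_before, x$n_after))
  invisible(x)
}

#' Frequency-based SNP pruning
#'
#' Removes every site whose absolute allele-frequency difference
#' between the two source populations is below `d_f`, keeping the most
#' ancestry-informative SNPs. Gaps and inter-site recombination
#' probabilities are recomputed across removed sites.
#'
#' @param sites a [site_table()].
#' @param genomes a [phased_genome()] or list of them aligned to
#'   `sites`.
#' @param d_f minimum allele-frequency difference, in `[0, 1]`.
#' @return List with `sites`, `genomes` (same shape as the input) and
#'   `report` (a `prune_report`).
#' @export
frequency_prune <- function(sites, genomes, d_f) {
  stopifnot(d_f >= 0, d_f <= 1)
  single <- inherits(genomes, "phased_genome")
  if (single) genomes <- list(genomes)
  keep <- which(abs(sites$freqA - sites$freqB) >= d_f)
  if (length(keep) == 0L) {
    stop(sprintf(
      "frequency pruning at d_f = %g removed every site; lower the threshold",
      d_f))
  }
  out_sites <- subset_sites(sites, keep)
  out_genomes <- lapply(genomes, subset_genome, keep = keep)
  list(sites = out_sites,
       genomes = if (single) out_genomes[[1L]] else out_genomes,
       report = prune_report(sites, out_sites, "frequency", d_f))
}

# r^2 between two binary haplotype columns; 0 when either is
# monomorphic in the panel.
hap_r2 <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Greedy windowed r^2 thinning in the style of PLINK's
#' `--indep-pairwise`: within each window of `window` SNPs, while any
#' retained pair has `r^2 > r2_max`, the later SNP of the offending
#' pair is dropped; the window then advances by `step` SNPs.
#' r^2 is estimated from the haplotypes in `genomes`.
#'
#' @inheritParams frequency_prune
#' @param window window size in SNPs.
#' @param step window advance in SNPs.
#' @param r2_max maximum tolerated pairwise r^2.
#' @return As [frequency_prune()].
#' @export
ld_prune <- function(sites, genomes, window = 50L, step = 5L, r2_max = 0.1) {
  stopifnot(window >= 2L, step >= 1L, r2_max >= 0)
  single <- inherits(genomes, "phased_genome")
  if (single) genomes <- list(genomes)
  H <- do.call(rbind, lapply(genomes, function(g) rbind(g$h1, g$h2)))
  removed <- rep(FALSE, nrow(sites))
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win <- win[!removed[win]]
      if (length(win) >= 2L) {
        repeat {
          dropped <- FALSE
          for (a in seq_len(length(win) - 1L)) {
            for (b in (a + 1L):length(win)) {
              if (removed[win[b]] || removed[win[a]]) next
              if (hap_r2(H[, win[a]], H[, win[b]]) > r2_max) {
                removed[win[b]] <- TRUE
                dropped <- TRUE
              }
            }
          }
          win <- win[!removed[win]]
          if (!dropped || length(win) < 2L) break
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  keep <- which(!removed)
  if (length(keep) == 0L) stop("LD pruning removed every site")
  out_sites <- subset_sites(sites, keep)
  out_genomes <- lapply(genomes, subset_genome, keep = keep)
  list(sites = out_sites,
       genomes = if (single) out_genomes[[1L]] else out_genomes,
       report = prune_report(sites, out_sites, "ld", r2_max))
}

# Viterbi decoding of a 2-state (A/B) per-haplotype ancestry HMM.
# Returns the decoded state per site (0 = A, 1 = B).
viterbi_ancestry <- function(h, sites, switch_rate,
                             switch_cap = .default_switch_cap) {
  n <- length(h)
  fA <- pmin(pmax(sites$freqA, 1e-6), 1 - 1e-6)
  fB <- pmin(pmax(sites$freqB, 1e-6), 1 - 1e-6)
  leA <- log(ifelse(h == 1, fA, 1 - fA))
  leB <- log(ifelse(h == 1, fB, 1 - fB))
  out <- integer(n)
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    m <- length(idx)
    sw <- pmin(sites$gap_bp[idx] * switch_rate, switch_cap)
    lsw <- log(sw); lst <- log1p(-sw)
    dA <- numeric(m); dB <- numeric(m)
    ptrA <- integer(m); ptrB <- integer(m)   # 1 = came from the other state
    dA[1L] <- log(0.5) + leA[idx[1L]]
    dB[1L] <- log(0.5) + leB[idx[1L]]
    if (m > 1L) for (i in 2:m) {
      stayA <- dA[i - 1L] + lst[i]; fromB <- dB[i - 1L] + lsw[i]
      if (stayA >= fromB) { dA[i] <- stayA; ptrA[i] <- 0L }
      else { dA[i] <- fromB; ptrA[i] <- 1L }
      stayB <- dB[i - 1L] + lst[i]; fromA <- dA[i - 1L] + lsw[i]
      if (stayB >= fromA) { dB[i] <- stayB; ptrB[i] <- 0L }
      else { dB[i] <- fromA; ptrB[i] <- 1L }
      dA[i] <- dA[i] + leA[idx[i]]
      dB[i] <- dB[i] + leB[idx[i]]
    }
    z <- integer(m)
    z[m] <- as.integer(dB[m] > dA[m])
    if (m > 1L) for (i in m:2) {
      came_from_other <- if (z[i] == 0L) ptrA[i] else ptrB[i]
      z[i - 1L] <- if (came_from_other == 1L) 1L - z[i] else z[i]
    }
    out[idx] <- z
  }
  out
}

#' Phase-switch error cleanup
#'
#' Decodes per-haplotype ancestry tracts with a rough 2-state HMM
#' (Viterbi), then looks for positions where the two haplotypes switch
#' ancestry in opposite directions within `min_tract` bp of each other
#' -- the signature of a spurious phase switch splitting two long
#' tracts -- and flips the phase of the downstream segment there.
#' Genotypes (`h1[i] + h2[i]`) are never altered; only the phase is.
#'
#' Also returns a reduced effective phase-switch rate to use in
#' inference: with `pp` known, the expected number of switch points is
#' `pp` times the covered genome length, and every corrected event
#' removes one of them, so `reduced_pp = pp * (expected - corrected) /
#' expected`, floored at `pp / 10`.
#'
#' @param genome a [phased_genome()].
#' @param sites a [site_table()].
#' @param pp the assumed per-bp phase-switch error rate of the input.
#' @param min_tract maximum bp separation of an opposite double switch
#'   treated as a phasing artifact (default 1e5 bp, about 0.1 cM at
#'   1 cM/Mb).
#' @param switch_rate_guess rough per-bp ancestry switch rate of the
#'   decoding HMM.
#' @return List with `genome` (re-phased), `reduced_pp`, `n_detected`
#'   (opposite double-switch events seen) and `n_corrected`.
#' @export
phase_cleanup <- function(genome, sites, pp, min_tract = 1e5,
                          switch_rate_guess = 1e-7) {
  if (min_tract <= 0) stop("min_tract must be positive")
  h1 <- genome$h1; h2 <- genome$h2
  n_detected <- 0L; n_corrected <- 0L
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    sub <- subset_sites(sites, idx)
    z1 <- viterbi_ancestry(h1[idx], sub, switch_rate_guess)
    z2 <- viterbi_ancestry(h2[idx], sub, switch_rate_guess)
    s1 <- which(diff(z1) != 0) + 1L      # switch at this site index
    s2 <- which(diff(z2) != 0) + 1L
    d1 <- z1[s1]                          # direction: state switched to
    d2 <- z2[s2]
    pos <- sub$pos_bp
    flips <- integer(0)
    used2 <- rep(FALSE, length(s2))
    for (a in seq_along(s1)) {
      cand <- which(!used2 & d2 != d1[a])
      if (length(cand) == 0L) next
      j <- cand[which.min(abs(pos[s2[cand]] - pos[s1[a]]))]
      gap <- abs(pos[s2[j]] - pos[s1[a]])
      n_detected <- n_detected + 1L
      if (gap <= min_tract) {
        used2[j] <- TRUE
        n_corrected <- n_corrected + 1L
        flips <- c(flips, max(s1[a], s2[j]))
      }
    }
    if (length(flips) > 0L) {
      parity <- rep(0L, length(idx))
      for (f in flips) parity[f:length(idx)] <- parity[f:length(idx)] + 1L
      swap <- parity %% 2L == 1L
      g1 <- h1[idx]; g2 <- h2[idx]
      h1[idx][swap] <- g2[swap]
      h2[idx][swap] <- g1[swap]
    }
  }
  genome_bp <- sum(vapply(unique(sites$chrom), function(ch) {
    max(sites$pos_bp[sites$chrom == ch])
  }, numeric(1)))
  expected <- pp * genome_bp
  reduced_pp <- if (expected <= 0) {
    0
  } else {
    max(pp * max(expected - n_corrected, 0) / expected, pp / 10)
  }
  list(genome = phased_genome(h1, h2, genome$sample_id),
       reduced_pp = reduced_pp,
       n_detected = n_detected, n_corrected = n_corrected)
}
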