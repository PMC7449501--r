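# SNP pruning and phase-switch cleanup.

make_sites <- function(freqA, freqB, pos = NULL, chrom = "chr1") {
  n <- length(freqA)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = n)
  site_table(chrom, pos, freqA, freqB, cM = pos * 1e-6 * 100 / 100)
}

test_that("frequency_prune removes sites below the |dAF| threshold", {
  sites <- make_sites(c(0.70, 0.95, 1.0, 0.6, 0.5),
                      c(0.70, 0.10, 0.0, 0.4, 0.5))
  g <- random_genome(5, seed = 1)
  out <- frequency_prune(sites, g, d_f = 0.5)
  expect_equal(out$sites$freqA, c(0.95, 1.0))
  expect_equal(out$report$n_before, 5L)
  expect_equal(out$report$n_after, 2L)
  expect_length(out$genomes$h1, 2L)
  # d_f = 0: identity
  out0 <- frequency_prune(sites, g, d_f = 0)
  expect_equal(nrow(out0$sites), 5L)
  # enumerated example: |dAF| = {1.0, 0.2, 0.0} -> 1 survivor
  s3 <- make_sites(c(1.0, 0.6, 0.5), c(0.0, 0.4, 0.5))
  out3 <- frequency_prune(s3, random_genome(3, seed = 2), d_f = 0.5)
  expect_equal(nrow(out3$sites), 1L)
  # removing everything is an error naming the threshold
  expect_error(frequency_prune(s3, random_genome(3, seed = 2), d_f = 1.01),
               "d_f")
  expect_error(frequency_prune(make_sites(0.5, 0.5),
                               random_genome(1, seed = 3), d_f = 0.5),
               "0.5")
})

test_that("pruning is idempotent and keeps the most informative sites", {
  set.seed(31)
  n <- 200
  sites <- make_sites(runif(n), runif(n))
  g <- random_genome(n)
  once <- frequency_prune(sites, g, d_f = 0.3)
  twice <- frequency_prune(once$sites, once$genomes, d_f = 0.3)
  expect_equal(twice$sites, once$sites)
  expect_identical(twice$genomes$h1, once$genomes$h1)
  d_kept <- abs(once$sites$freqA - once$sites$freqB)
  removed <- setdiff(seq_len(n),
                     match(once$sites$pos_bp, sites$pos_bp))
  d_removed <- abs(sites$freqA - sites$freqB)[removed]
  expect_gte(min(d_kept), max(d_removed))
})

test_that("pruning recomputes gaps and recombination across removed sites", {
  # sites 1 Mb apart under a uniform 1 cM/Mb map
  pos <- c(1e6, 2e6, 3e6)
  sites <- site_table("chr1", pos, freqA = c(1, 0.6, 1),
                      freqB = c(0, 0.4, 0), cM = pos / 1e6)
  out <- frequency_prune(sites, random_genome(3, seed = 4), d_f = 0.5)
  expect_equal(out$sites$gap_bp[2], 2e6)
  expect_equal(out$sites$rec_prob[2], 0.02)   # 2 cM
})

test_that("ld_prune drops one SNP of each high-r2 pair", {
  set.seed(41)
  n <- 12; hpanel <- 40
  H <- matrix(rbinom(hpanel * n, 1, 0.5), hpanel, n)
  H[, 7] <- H[, 3]            # duplicated column, r2 = 1
  genomes <- lapply(seq_len(hpanel / 2), function(i) {
    phased_genome(H[2 * i - 1, ], H[2 * i, ], sprintf("s%d", i))
  })
  sites <- make_sites(runif(n, 0.8, 1), runif(n, 0, 0.2))
  out <- ld_prune(sites, genomes, window = 12, step = 3, r2_max = 0.9)
  kept <- match(out$sites$pos_bp, sites$pos_bp)
  expect_true(xor(3 %in% kept, 7 %in% kept))
  # independent columns survive r2_max = 1
  out1 <- ld_prune(sites, genomes, window = 12, step = 3, r2_max = 1)
  expect_equal(nrow(out1$sites), n)
  # three sites, pairwise r2 = {1, 0, 0}: two survive
  H3 <- cbind(H[, 1], H[, 1], rbinom(hpanel, 1, 0.5))
  g3 <- lapply(seq_len(hpanel / 2), function(i) {
    phased_genome(H3[2 * i - 1, ], H3[2 * i, ], sprintf("s%d", i))
  })
  out3 <- ld_prune(make_sites(rep(0.9, 3), rep(0.1, 3)), g3,
                   window = 3, step = 1, r2_max = 0.5)
  expect_equal(nrow(out3$sites), 2L)
})

test_that("phase_cleanup is a no-op on clean input and never edits genotypes", {
  sim <- tiny_sim(seed = 411, n_i = 1, t = 0.6)
  pr <- frequency_prune(sim$sites, sim$genomes, 0.5)
  g <- pr$genomes[[1]]
  out <- phase_cleanup(g, pr$sites, pp = 2e-5)
  expect_lte(out$reduced_pp, 2e-5)
  expect_identical(out$genome$h1 + out$genome$h2, g$h1 + g$h2)
  expect_error(phase_cleanup(g, pr$sites, pp = 2e-5, min_tract = 0),
               "min_tract")
})

test_that("phase_cleanup corrects an injected mid-chromosome switch", {
  # one chromosome; h1 carries pop-A ancestry, h2 pop-B; a single
  # phase switch at the midpoint swaps the tails
  set.seed(421)
  n <- 600
  pos <- sort(sample.int(5e6, n))
  fA <- runif(n, 0.85, 1); fB <- runif(n, 0, 0.15)
  sites <- site_table("chr1", pos, fA, fB, cM = pos * 1e-6)
  h1 <- rbinom(n, 1, fA); h2 <- rbinom(n, 1, fB)
  cut <- which(pos > 2.5e6)[1]
  e1 <- c(h1[1:(cut - 1)], h2[cut:n])
  e2 <- c(h2[1:(cut - 1)], h1[cut:n])
  out <- phase_cleanup(phased_genome(e1, e2), sites, pp = 2e-5)
  expect_gte(mean(out$genome$h1 == h1 & out$genome$h2 == h2), 0.99)
  expect_identical(out$genome$h1 + out$genome$h2, e1 + e2)
  expect_gte(out$n_corrected, 1L)
})

test_that("phase cleanup does not hurt inference on phase-corrupted data", {
  # paired comparison over 5 seeds at desk scale: mean error with
  # cleanup <= mean error without
  # strong divergence so the per-haplotype ancestry decoding that
  # drives the cleanup is accurate
  errs <- vapply(1:5, function(sd) {
    sim <- tiny_sim(seed = 500 + sd, n_i = 1, pp = 2e-5, t = 0.6,
                    L = 3e7)
    pr <- frequency_prune(sim$sites, sim$genomes, 0.5)
    truth <- list(sim$truth[[1]]$generations[[1]]$proportions)
    raw <- fit_ml(pr$genomes[[1]], pr$sites, K = 1, pp = 2e-5,
                  options = fit_options(restarts = 2, seed = 600 + sd))
    cl <- phase_cleanup(pr$genomes[[1]], pr$sites, pp = 2e-5)
    cln <- fit_ml(cl$genome, pr$sites, K = 1, pp = cl$reduced_pp,
                  options = fit_options(restarts = 2, seed = 600 + sd))
    c(raw = mean_error(truth, list(raw$m0_hat), 1)$mean_error,
      cln = mean_error(truth, list(cln$m0_hat), 1)$mean_error)
  }, numeric(2))
  expect_lte(mean(errs["cln", ]), mean(errs["raw", ]))
})
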