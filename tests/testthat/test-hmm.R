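# Transition/emission model, divide-and-conquer step, forward
# likelihood.

test_that("per-bit step probabilities are linear in d and clamped", {
  # zero distance: identity
  expect_equal(ancestry_step_prob(0, 0, 0, 1e-7, 1e-7), 1)
  expect_equal(ancestry_step_prob(0, 1, 0, 1e-7, 1e-7), 0)
  expect_equal(phase_step_prob(0, 1, 0, 1e-5), 0)
  # d * rate
  expect_equal(ancestry_step_prob(0, 1, 1000, 1e-7, 3e-7), 1e-4)
  expect_equal(ancestry_step_prob(0, 0, 1000, 1e-7, 3e-7), 0.9999)
  expect_equal(ancestry_step_prob(1, 0, 1000, 1e-7, 3e-7), 3e-4)
  expect_equal(phase_step_prob(0, 1, 500, 2e-5), 0.01)
  expect_equal(phase_step_prob(1, 1, 500, 2e-5), 0.99)
  expect_equal(phase_step_prob(0, 1, 500, 0), 0)
  expect_equal(phase_step_prob(0, 0, 500, 0), 1)
  # clamping at switch_cap when d * rate exceeds it
  expect_equal(ancestry_step_prob(0, 1, 1e7, 1e-6, 1e-6), 0.5)
  expect_equal(ancestry_step_prob(0, 0, 1e7, 1e-6, 1e-6), 0.5)
  expect_equal(ancestry_step_prob(0, 1, 1e7, 1e-6, 1e-6, switch_cap = 0.3),
               0.3)
  expect_error(ancestry_step_prob(0, 1, -5, 1e-7, 1e-7), "non-negative")
  # recombination bit
  expect_equal(recomb_step_prob(0, 1, 0), 0)
  expect_equal(recomb_step_prob(0, 0, 0), 1)
  expect_equal(recomb_step_prob(0, 1, 0.01), 0.01)
  for (rp in c(0, 0.17, 0.5)) {
    expect_equal(recomb_step_prob(0, 1, rp) + recomb_step_prob(0, 0, rp), 1)
  }
  expect_error(recomb_step_prob(0, 1, 0.7), "0, 0.5")
})

test_that("transition_prob is the product of independent per-bit steps", {
  m <- founder_model(1, 1e-7, 1e-7, pp = 1e-5)
  s <- encode_ac(0, c(0, 1), integer(0), 1)
  expect_equal(transition_prob(s, s, 100, 0, m),
               (1 - 1e-3) * (1 - 1e-5)^2, tolerance = 1e-12)
  # rows of p_t(.|from) are normalized over all targets
  for (K in 1:2) {
    mK <- random_model(K, seed = 20 + K)
    Tm <- dense_T_oracle(1500, 0.02, mK)
    expect_equal(colSums(Tm), rep(1, n_states(K)), tolerance = 1e-12)
  }
  # identity transition at d = 0, rec_prob = 0
  m2 <- random_model(2, seed = 31)
  Tm0 <- dense_T_oracle(0, 0, m2)
  expect_equal(Tm0, diag(n_states(2)), tolerance = 0)
  # package dense matrix agrees with the scalar-product oracle
  expect_equal(transition_matrix(1500, 0.02, m2),
               dense_T_oracle(1500, 0.02, m2), tolerance = 1e-14)
})

test_that("emission_prob reads the routed founder's allele frequency", {
  # fixed difference, pure A x B routing: probability 1
  s_ok <- encode_ac(0, c(0, 1), integer(0), 1)  # h1 -> founder 1 (A)
  expect_equal(emission_prob(s_ok, c(1, 0), freqA = 1, freqB = 0, K = 1), 1)
  # impossible routing: h1 -> B founder carrying frequency 0
  s_bad <- encode_ac(1, c(0, 1), integer(0), 1) # h1 -> founder 2 (B)
  expect_equal(emission_prob(s_bad, c(1, 0), freqA = 1, freqB = 0, K = 1), 0)
  # generic product of the two observed-allele frequencies
  s_ab <- encode_ac(0, c(0, 1), integer(0), 1)
  expect_equal(emission_prob(s_ab, c(1, 1), freqA = 0.8, freqB = 0.3, K = 1),
               0.8 * 0.3)
  expect_error(emission_prob(0, c(1, 1), freqA = 1.2, freqB = 0.3, K = 1),
               "frequencies")
})

test_that("init_distribution is the product law: uniform P/R, stationary C", {
  # both founders 50:50: uniform over the 8 states
  m <- founder_model(1, 1e-7, 1e-7, pp = 0)
  expect_equal(init_distribution(m), rep(1 / 8, 8))
  # founder 1 pure A (m0 = 1): no mass on C[1] = 1 states
  mp <- founder_model(1, rateAB = c(1e-300, 1e-7), rateBA = c(1e-7, 1e-7))
  v <- init_distribution(mp)
  c1 <- vapply(0:7, function(s) decode_ac(s, 1)$C[1], integer(1))
  expect_true(all(v[c1 == 1L] == 0))
  expect_equal(sum(v), 1)
  # normalization for random models
  for (K in 1:3) {
    expect_equal(sum(init_distribution(random_model(K, seed = 40 + K))), 1,
                 tolerance = 1e-12)
  }
})

test_that("d&c forward step equals the dense matrix-vector product", {
  # full dense comparison at K = 1, 2 over random draws
  set.seed(52)
  for (K in 1:2) {
    for (rep in 1:10) {
      m <- random_model(K)
      v <- runif(n_states(K)); v <- v / sum(v)
      d <- sample(10:50000, 1); rp <- runif(1, 0, 0.5)
      dense <- as.vector(dense_T_oracle(d, rp, m) %*% v)
      fast <- forward_step_dc(v, d, rp, m)
      expect_equal(fast, dense, tolerance = 1e-12)
      expect_equal(sum(fast), sum(v), tolerance = 1e-12)  # mass conserved
    }
  }
  # K = 3: row-wise dense oracle on random rows + mass conservation
  m3 <- random_model(3, seed = 53)
  v3 <- runif(n_states(3)); v3 <- v3 / sum(v3)
  fast3 <- forward_step_dc(v3, 2500, 0.03, m3)
  expect_equal(sum(fast3), 1, tolerance = 1e-10)
  for (to in sample(0:(n_states(3) - 1L), 64)) {
    expect_equal(fast3[to + 1L],
                 sum(dense_row_oracle(to, 2500, 0.03, m3) * v3),
                 tolerance = 1e-12)
  }
  # identity transition reproduces the input
  expect_equal(forward_step_dc(v3, 0, 0, m3), v3)
})

test_that("d&c step costs O(N log N) multiply-adds, not O(N^2)", {
  for (K in 2:3) {
    N <- n_states(K)
    b <- ac_bits(K)
    m <- random_model(K, seed = 60 + K)
    v <- rep(1 / N, N)
    t01 <- c(min(1000 * m$pp, 0.5), pmin(1000 * m$rateAB, 0.5),
             rep(0.01, 2^K - 2))
    t10 <- c(min(1000 * m$pp, 0.5), pmin(1000 * m$rateBA, 0.5),
             rep(0.01, 2^K - 2))
    res <- admixped:::dc_step_counted(v, t01, t10)
    expect_equal(res$probs, forward_step_dc(v, 1000, 0.01, m),
                 tolerance = 1e-12)
    expect_lte(res$multiply_adds, 4 * N * log2(N))
    expect_lt(res$multiply_adds, N^2)
  }
})

test_that("forward likelihood equals exhaustive path enumeration", {
  set.seed(71)
  # K = 1, 6 sites: 8^6 paths
  sites1 <- random_sites(6)
  g1 <- random_genome(6)
  m1 <- random_model(1)
  expect_equal(loglikelihood(g1, sites1, m1),
               enumeration_loglik(g1, sites1, m1), tolerance = 1e-10)
  # K = 2, 3 sites: 128^3 paths
  sites2 <- random_sites(3)
  g2 <- random_genome(3)
  m2 <- random_model(2)
  expect_equal(loglikelihood(g2, sites2, m2),
               enumeration_loglik(g2, sites2, m2), tolerance = 1e-10)
  # multi-chromosome likelihood is the sum of per-chromosome chains
  sitesA <- random_sites(4, chrom = "chr1")
  sitesB <- random_sites(3, chrom = "chr2")
  both <- site_table(c(sitesA$chrom, sitesB$chrom),
                     c(sitesA$pos_bp, sitesB$pos_bp),
                     c(sitesA$freqA, sitesB$freqA),
                     c(sitesA$freqB, sitesB$freqB),
                     rec_prob = c(sitesA$rec_prob, sitesB$rec_prob))
  gA <- random_genome(4); gB <- random_genome(3)
  gboth <- phased_genome(c(gA$h1, gB$h1), c(gA$h2, gB$h2))
  expect_equal(loglikelihood(gboth, both, m1),
               loglikelihood(gA, sitesA, m1) + loglikelihood(gB, sitesB, m1),
               tolerance = 1e-12)
})

test_that("with all emissions 1 the path probabilities sum to 1", {
  set.seed(81)
  n <- 25
  sites <- site_table("chr1", cumsum(sample(100:3000, n, TRUE)),
                      freqA = rep(1, n), freqB = rep(1, n),
                      rec_prob = c(NA, runif(n - 1, 0, 0.5)))
  g <- phased_genome(rep(1, n), rep(1, n))
  for (K in 1:2) {
    expect_equal(loglikelihood(g, sites, random_model(K)), 0,
                 tolerance = 1e-10)
  }
})

test_that("the intro fixed-difference example reproduces through K=1", {
  s1 <- site_table("chr1", 1, freqA = 1, freqB = 0, rec_prob = NA)
  g10 <- phased_genome(1, 0); g01 <- phased_genome(0, 1)
  # one parent pure A, the other pure B: unordered heterozygote
  # probability 1 (each phased ordering has probability 0.5)
  pure <- founder_model(1, rateAB = c(1e-300, 1e-4),
                        rateBA = c(1e-4, 1e-300))
  expect_equal(exp(loglikelihood(g10, s1, pure)), 0.5, tolerance = 1e-9)
  expect_equal(exp(loglikelihood(g10, s1, pure)) +
                 exp(loglikelihood(g01, s1, pure)), 1, tolerance = 1e-9)
  # both parents 50:50 admixed: heterozygote probability 0.5
  half <- founder_model(1, 1e-7, 1e-7)
  expect_equal(exp(loglikelihood(g10, s1, half)) +
                 exp(loglikelihood(g01, s1, half)), 0.5, tolerance = 1e-9)
})

test_that("likelihood is invariant under pedigree-half relabeling", {
  set.seed(91)
  for (K in 1:2) {
    n <- 40
    sites <- random_sites(n)
    g <- random_genome(n)
    m <- random_model(K)
    expect_equal(loglikelihood(g, sites, m),
                 loglikelihood(g, sites, swap_halves(m)), tolerance = 1e-10)
  }
})

test_that("a matched pure model beats a 50:50 model on unadmixed data", {
  sim <- tiny_sim(seed = 131, admix_frac = 1, n_i = 2)
  pr <- frequency_prune(sim$sites, sim$genomes, 0.5)
  pure <- founder_model(1, rateAB = 1e-10, rateBA = 1e-5)   # m0 ~ 1
  half <- founder_model(1, 1e-7, 1e-7)                       # m0 = 0.5
  for (g in pr$genomes) {
    expect_gt(loglikelihood(g, pr$sites, pure),
              loglikelihood(g, pr$sites, half))
  }
})

test_that("loglikelihood validates its inputs", {
  m <- founder_model(1, 1e-7, 1e-7)
  sites <- random_sites(5, seed = 101)
  g <- random_genome(5, seed = 102)
  expect_error(loglikelihood(random_genome(4), sites, m), "different numbers")
  bad <- sites; bad$freqA[2] <- NaN
  expect_error(loglikelihood(g, bad, m), "non-finite")
})
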