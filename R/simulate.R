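# Wright-Fisher admixture simulator with tract tracking.
#
# Two ancestral populations diverged t (coalescent-scaled) time units
# ago are emulated by a Balding-Nichols frequency model with
# F = 1 - exp(-t); founder haplotypes are drawn site-independently
# from the population frequencies. An admixed population is formed by
# merging founder haplotypes (fraction admix_frac from population A)
# into diploids and evolving g generations of random mating, drift and
# recombination on a hotspot-like piecewise-constant genetic map.
# Every haplotype is carried as a mosaic of founder-haplotype tracts,
# so true admixture proportions and tract lists of every ancestor are
# known exactly.

#' Simulation configuration
#'
#' Defaults follow the standard simulation design for this model:
#' 1000 founder haplotypes, 22 chromosomes, Ne = 10000, mutation and
#' recombination rates 1e-8 per bp per generation, populations split
#' t = 0.2 (times Ne) ago, admixture g = 10 generations ago, 10
#' sampled individuals, frequency-pruning threshold 0.5, and no phase
#' errors unless requested. `L` defaults to 5e8 (the shorter standard
#' genome); pass 3e9 for the full-scale design.
#'
#' @param n_h number of founder haplotypes in the admixed population
#'   (also the per-population reference panel size is `n_h / 2`).
#' @param n_c number of chromosomes (equal length).
#' @param Ne effective population size.
#' @param L total genome length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param rho mean per-bp per-generation recombination rate.
#' @param t population split time, scaled by Ne (divergence
#'   `F = 1 - exp(-t)`).
#' @param g generations since the single admixture pulse.
#' @param n_i number of individuals sampled for inference.
#' @param d_f default frequency-pruning threshold carried in the
#'   config.
#' @param pp per-bp phase-switch error rate injected into sampled
#'   genomes.
#' @param admix_frac fraction of generation-0 haplotypes drawn from
#'   population A.
#' @param K_max deepest ancestor generation recorded in the truth.
#' @param map_segments piecewise-constant map segments per chromosome.
#' @param map_sdlog log-sd of the log-normal hotspot multipliers
#'   (mean multiplier 1).
#' @param seed integer seed driving all randomness of the run.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_h = 1000L, n_c = 22L, Ne = 10000, L = 5e8,
                       mu = 1e-8, rho = 1e-8, t = 0.2, g = 10L,
                       n_i = 10L, d_f = 0.5, pp = 0, admix_frac = 0.5,
                       K_max = 3L, map_segments = 20L, map_sdlog = 1,
                       seed = NULL) {
  stopifnot(n_h >= 4L, n_h %% 2L == 0L, n_c >= 1L, Ne > 0, L > 0,
            mu > 0, rho > 0, t >= 0, g >= 0L, n_i >= 1L,
            d_f >= 0, d_f <= 1, pp >= 0,
            admix_frac >= 0, admix_frac <= 1, K_max >= 1L)
  cfg <- list(n_h = as.integer(n_h), n_c = as.integer(n_c), Ne = Ne, L = L,
              mu = mu, rho = rho, t = t, g = as.integer(g),
              n_i = as.integer(n_i), d_f = d_f, pp = pp,
              admix_frac = admix_frac, K_max = as.integer(K_max),
              map_segments = as.integer(map_segments),
              map_sdlog = map_sdlog, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# Hotspot-like piecewise-constant genetic map: per chromosome,
# map_segments equal-length segments whose per-bp rates are rho times
# log-normal multipliers with mean 1.
simulate_genetic_map <- function(cfg) {
  Lc <- floor(cfg$L / cfg$n_c)
  seg_len <- Lc / cfg$map_segments
  maps <- lapply(seq_len(cfg$n_c), function(ci) {
    mult <- exp(rnorm(cfg$map_segments,
                      -cfg$map_sdlog^2 / 2, cfg$map_sdlog))
    rate <- cfg$rho * mult                       # Morgans per bp
    ends <- seg_len * seq_len(cfg$map_segments)
    cumM <- cumsum(rate * seg_len)               # Morgans at segment ends
    data.frame(chrom = paste0("chr", ci),
               start = c(0, head(ends, -1L)), end = ends,
               rate = rate, cumM_end = cumM)
  })
  do.call(rbind, maps)
}

# Cumulative genetic position (Morgans) of bp positions on one
# chromosome of the map.
map_cum_morgans <- function(map_chr, pos) {
  seg <- findInterval(pos - 1e-9, map_chr$end) + 1L
  seg <- pmin(seg, nrow(map_chr))
  base <- c(0, head(map_chr$cumM_end, -1L))
  base[seg] + (pos - map_chr$start[seg]) * map_chr$rate[seg]
}

# Inverse of map_cum_morgans: bp position at genetic position u.
map_inv_morgans <- function(map_chr, u) {
  cum0 <- c(0, head(map_chr$cumM_end, -1L))
  seg <- findInterval(u, map_chr$cumM_end) + 1L
  seg <- pmin(seg, nrow(map_chr))
  map_chr$start[seg] + (u - cum0[seg]) / map_chr$rate[seg]
}

#' Simulate diverged founder haplotype panels
#'
#' Draws segregating sites at the neutral coalescent density
#' `4 Ne mu L * H(n_h - 1)`, per-site ancestral frequencies uniform,
#' population frequencies from a Balding-Nichols law with
#' `F = 1 - exp(-t)`, and two panels of `n_h / 2` haplotypes each by
#' site-independent Bernoulli draws. Sites monomorphic across the
#' combined panel are dropped.
#'
#' @param cfg a [sim_config()]. Randomness comes from the current RNG
#'   state (seed it, or use [simulate_admixture()] which seeds once).
#' @param map optional genetic map from `simulate_genetic_map()`;
#'   generated if missing.
#' @return List with `panel` (haplotype x site 0/1 matrix; rows
#'   `1..n_h/2` population A, the rest population B), `sites` (a
#'   [site_table()] whose `freqA`/`freqB` are the realized panel
#'   frequencies), `map`, `n_popA` (panel rows from A).
#' @export
simulate_founders <- function(cfg, map = NULL) {
  if (is.null(map)) map <- simulate_genetic_map(cfg)
  nh2 <- cfg$n_h %/% 2L
  a_n <- sum(1 / seq_len(cfg$n_h - 1L))
  S <- rpois(1L, 4 * cfg$Ne * cfg$mu * cfg$L * a_n)
  if (S < 2L) stop("simulated region contains fewer than 2 SNPs")
  Lc <- floor(cfg$L / cfg$n_c)
  chrom_idx <- sort(sample.int(cfg$n_c, S, replace = TRUE))
  pos <- integer(S)
  for (ci in unique(chrom_idx)) {
    ii <- which(chrom_idx == ci)
    pos[ii] <- sort(sample.int(Lc, length(ii), replace = FALSE))
  }
  p_anc <- runif(S)
  FST <- 1 - exp(-cfg$t)
  if (FST == 0) {
    pA <- pB <- p_anc
  } else {
    shape <- (1 - FST) / FST
    pA <- rbeta(S, p_anc * shape, (1 - p_anc) * shape)
    pB <- rbeta(S, p_anc * shape, (1 - p_anc) * shape)
  }
  panelA <- matrix(rbinom(nh2 * S, 1L, rep(pA, each = nh2)), nrow = nh2)
  panelB <- matrix(rbinom(nh2 * S, 1L, rep(pB, each = nh2)), nrow = nh2)
  freqA <- colMeans(panelA)
  freqB <- colMeans(panelB)
  seg <- (freqA + freqB) > 0 & (freqA + freqB) < 2
  if (!any(seg)) stop("no segregating sites in the combined panel")
  chrom <- paste0("chr", chrom_idx[seg])
  pos <- pos[seg]
  cM <- numeric(sum(seg))
  for (ci in unique(chrom_idx[seg])) {
    lab <- paste0("chr", ci)
    ii <- which(chrom == lab)
    cM[ii] <- 100 * map_cum_morgans(map[map$chrom == lab, ], pos[ii])
  }
  sites <- site_table(chrom = chrom, pos_bp = pos,
                      freqA = freqA[seg], freqB = freqB[seg], cM = cM)
  list(panel = rbind(panelA, panelB)[, seg, drop = FALSE],
       sites = sites, map = map, n_popA = nh2)
}

# --- tract machinery -------------------------------------------------
# A haplotype on one chromosome is a pair of parallel vectors:
#   ends: tract end positions (bp, increasing, last = chromosome end)
#   ids : founder haplotype id of each tract (1..n_h; ids <= n_h/2 are
#         population A)

# Sub-tracts of `hap` covering the interval (a, b].
tract_extract <- function(hap, a, b) {
  i0 <- findInterval(a, hap$ends) + 1L   # first tract with end > a
  i1 <- i0
  while (hap$ends[i1] < b) i1 <- i1 + 1L
  ends <- hap$ends[i0:i1]
  ends[length(ends)] <- b
  list(ends = ends, ids = hap$ids[i0:i1])
}

tract_merge <- function(ends, ids) {
  if (length(ids) > 1L) {
    same <- c(ids[-1L] == ids[-length(ids)], FALSE)
    keep <- !same
    ends <- ends[keep]; ids <- ids[keep]
  }
  list(ends = ends, ids = ids)
}

# Meiosis on one chromosome: crossover mosaic of the parent's two
# haplotypes with the given crossover positions.
tract_recombine <- function(hapX, hapY, xo, start_hap) {
  if (length(xo) == 0L) return(if (start_hap == 1L) hapX else hapY)
  Lc <- hapX$ends[length(hapX$ends)]
  bounds <- c(0, xo, Lc)
  ends <- numeric(0); ids <- integer(0)
  cur <- start_hap
  for (s in seq_len(length(bounds) - 1L)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    if (b <= a) { cur <- 3L - cur; next }
    piece <- tract_extract(if (cur == 1L) hapX else hapY, a, b)
    ends <- c(ends, piece$ends); ids <- c(ids, piece$ids)
    cur <- 3L - cur
  }
  tract_merge(ends, ids)
}

# Fraction of a haplotype (list over chromosomes) in population A.
hap_popA_fraction <- function(hap_chroms, n_popA_ids) {
  a_len <- 0; tot <- 0
  for (hc in hap_chroms) {
    starts <- c(0, head(hc$ends, -1L))
    lens <- hc$ends - starts
    a_len <- a_len + sum(lens[hc$ids <= n_popA_ids])
    tot <- tot + sum(lens)
  }
  a_len / tot
}

# Tract list (population labels) of one haplotype, as a data.frame.
hap_tracts <- function(hap_chroms, n_popA_ids) {
  out <- lapply(seq_along(hap_chroms), function(ci) {
    hc <- hap_chroms[[ci]]
    tm <- tract_merge(hc$ends, as.integer(hc$ids <= n_popA_ids))
    starts <- c(0, head(tm$ends, -1L))
    data.frame(chrom = paste0("chr", ci), start_bp = starts + 1,
               end_bp = tm$ends,
               pop = ifelse(tm$ids == 1L, "A", "B"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evolve an admixed Wright-Fisher population with tract tracking
#'
#' Generation 0 pairs founder haplotypes into `n_h / 2` diploids
#' (fraction `admix_frac` of haplotype slots drawn from the population
#' A panel). Each later generation draws, for every child, two
#' distinct parents uniformly; each transmitted gamete is a crossover
#' mosaic of the parent's two haplotypes with crossovers placed by a
#' Poisson process on the genetic map. The last `K_max` generations
#' and the full pedigree are retained so the true admixture
#' proportions of every recent ancestor of any sampled individual are
#' available.
#'
#' @param founders result of [simulate_founders()].
#' @param cfg a [sim_config()].
#' @return List with `population` (tract representation of the final
#'   generation), `history` (tract populations of generations
#'   `g - K_max .. g - 1`), `pedigree` (per-generation parent index
#'   matrices), `map`, `n_popA_ids` (founder haplotype ids belonging
#'   to population A), `Lc`.
#' @export
evolve_admixed <- function(founders, cfg) {
  nh2 <- cfg$n_h %/% 2L
  N_dip <- nh2
  Lc <- floor(cfg$L / cfg$n_c)
  map <- founders$map

  # generation-0 haplotype slots: A-panel ids are 1..nh2, B-panel ids
  # nh2+1..n_h
  n_slots <- 2L * N_dip
  nA <- round(cfg$admix_frac * n_slots)
  pick <- function(k, pool) {
    if (k <= length(pool)) sample(pool, k) else sample(pool, k, replace = TRUE)
  }
  slot_ids <- c(if (nA > 0L) pick(nA, seq_len(nh2)),
                if (n_slots - nA > 0L) pick(n_slots - nA, nh2 + seq_len(nh2)))
  slot_ids <- sample(slot_ids)     # shuffle before pairing into diploids
  new_hap <- function(id) lapply(seq_len(cfg$n_c), function(ci)
    list(ends = as.numeric(Lc), ids = as.integer(id)))
  pop <- lapply(seq_len(N_dip), function(i) {
    list(new_hap(slot_ids[2L * i - 1L]), new_hap(slot_ids[2L * i]))
  })

  chrom_maps <- split(map, map$chrom)[paste0("chr", seq_len(cfg$n_c))]
  G_c <- vapply(chrom_maps, function(m) m$cumM_end[nrow(m)], numeric(1))

  gamete <- function(parent) {
    lapply(seq_len(cfg$n_c), function(ci) {
      n_xo <- rpois(1L, G_c[ci])
      xo <- if (n_xo > 0L) {
        sort(map_inv_morgans(chrom_maps[[ci]], runif(n_xo, 0, G_c[ci])))
      } else numeric(0)
      tract_recombine(parent[[1L]][[ci]], parent[[2L]][[ci]], xo,
                      sample(1:2, 1L))
    })
  }

  pedigree <- vector("list", cfg$g)
  history <- list()
  keep_from <- max(cfg$g - cfg$K_max, 0L)
  if (cfg$g == 0L || keep_from == 0L) history[["0"]] <- pop
  if (cfg$g > 0L) for (gen in seq_len(cfg$g)) {
    parents <- t(vapply(seq_len(N_dip), function(i) sample(N_dip, 2L),
                        integer(2)))
    pop <- lapply(seq_len(N_dip), function(i) {
      list(gamete(pop[[parents[i, 1L]]]), gamete(pop[[parents[i, 2L]]]))
    })
    pedigree[[gen]] <- parents
    if (gen >= keep_from) history[[as.character(gen)]] <- pop
  }

  list(population = pop, history = history, pedigree = pedigree,
       map = map, n_popA_ids = nh2, Lc = Lc)
}

# Ancestor indices of individual `ind` (final generation) at `k`
# generations back, ordered left-to-right to match the pedigree tree:
# haplotype 1 of any child descends from its first listed parent.
ancestor_indices <- function(pedigree, g, ind, k) {
  cur <- ind
  for (back in seq_len(k)) {
    gen <- g - back + 1L
    cur <- as.vector(t(pedigree[[gen]][cur, , drop = FALSE]))
  }
  cur
}

#' Inject phase-switch errors into a phased genome
#'
#' Switch points are placed on each chromosome by a Poisson process at
#' rate `pp` per bp; between successive switch points the two
#' haplotypes are swapped (parity alternates). Genotypes are
#' unchanged.
#'
#' @param genome a [phased_genome()].
#' @param sites the [site_table()] the genome is aligned to.
#' @param pp per-bp phase-switch rate.
#' @param chrom_len chromosome length in bp (defaults to the last site
#'   position per chromosome).
#' @param seed optional seed for the switch-point draws.
#' @return A [phased_genome()]; the bp switch points are attached as
#'   attribute `"switch_points"` (list per chromosome).
#' @export
inject_phase_errors <- function(genome, sites, pp, chrom_len = NULL,
                                seed = NULL) {
  if (pp < 0) stop("pp must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  h1 <- genome$h1; h2 <- genome$h2
  switch_points <- list()
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    Lc <- if (is.null(chrom_len)) max(sites$pos_bp[idx]) else chrom_len
    n_sw <- rpois(1L, pp * Lc)
    sw <- sort(runif(n_sw, 0, Lc))
    switch_points[[chr]] <- sw
    if (n_sw == 0L) next
    parity <- findInterval(sites$pos_bp[idx], sw) %% 2L
    swap <- parity == 1L
    g1 <- h1[idx]; g2 <- h2[idx]
    h1[idx][swap] <- g2[swap]
    h2[idx][swap] <- g1[swap]
  }
  out <- phased_genome(h1, h2, genome$sample_id)
  attr(out, "switch_points") <- switch_points
  out
}

#' Simulate an admixed population and sampled phased genomes
#'
#' Full pipeline: founder panels, Wright-Fisher admixture with tract
#' tracking, assembly of sampled individuals' haplotypes from the
#' founder panel, truth records for ancestors up to `K_max`
#' generations, and optional phase-error injection.
#'
#' @param cfg a [sim_config()]. `cfg$seed` (if non-NULL) seeds all
#'   randomness of the run.
#' @return List of class `"admix_sim"` with elements `sites`
#'   ([site_table()]), `genomes` (list of [phased_genome()]), `truth`
#'   (list per sampled individual: `focal_proportion`,
#'   `focal_hap_proportions` (ancestry fraction of each transmitted
#'   gamete), and per generation k a list with `ancestors` (indices),
#'   `proportions`
#'   (population-A fraction per ancestor, left to right) and `tracts`),
#'   `map`, `config`, and `panel_freq_only` metadata.
#' @export
simulate_admixture <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  founders <- simulate_founders(cfg)
  evo <- evolve_admixed(founders, cfg)
  n_popA <- evo$n_popA_ids
  N_dip <- cfg$n_h %/% 2L
  sample_ids <- sample(N_dip, min(cfg$n_i, N_dip))

  sites <- founders$sites
  chrom_of <- sites$chrom
  pos_of <- sites$pos_bp

  assemble_hap <- function(hap_chroms) {
    out <- integer(nrow(sites))
    for (ci in seq_len(cfg$n_c)) {
      lab <- paste0("chr", ci)
      idx <- which(chrom_of == lab)
      if (length(idx) == 0L) next
      hc <- hap_chroms[[ci]]
      ti <- findInterval(pos_of[idx] - 1, hc$ends) + 1L
      fid <- hc$ids[ti]
      out[idx] <- founders$panel[cbind(fid, idx)]
    }
    out
  }

  genomes <- list()
  truth <- list()
  for (s in seq_along(sample_ids)) {
    ind_idx <- sample_ids[s]
    indiv <- evo$population[[ind_idx]]
    g1 <- assemble_hap(indiv[[1L]])
    g2 <- assemble_hap(indiv[[2L]])
    gen <- phased_genome(g1, g2, sprintf("sim_%02d", s))
    if (cfg$pp > 0) {
      gen <- inject_phase_errors(gen, sites, cfg$pp, chrom_len = evo$Lc)
    }
    genomes[[s]] <- gen

    prop_of_hap <- function(h) hap_popA_fraction(h, n_popA)
    hap_props <- c(prop_of_hap(indiv[[1L]]), prop_of_hap(indiv[[2L]]))
    focal <- mean(hap_props)
    anc <- list()
    for (k in seq_len(min(cfg$K_max, cfg$g))) {
      gen_idx <- cfg$g - k
      anc_pop <- evo$history[[as.character(gen_idx)]]
      ids <- ancestor_indices(evo$pedigree, cfg$g, ind_idx, k)
      props <- vapply(ids, function(a) {
        ai <- anc_pop[[a]]
        (prop_of_hap(ai[[1L]]) + prop_of_hap(ai[[2L]])) / 2
      }, numeric(1))
      tracts <- lapply(ids, function(a) {
        ai <- anc_pop[[a]]
        list(h1 = hap_tracts(ai[[1L]], n_popA),
             h2 = hap_tracts(ai[[2L]], n_popA))
      })
      anc[[k]] <- list(ancestors = ids, proportions = props,
                       tracts = tracts)
    }
    # focal_hap_proportions[w] is the ancestry fraction of the gamete
    # transmitted by parent w: the best estimate of that parent's
    # proportion available even to an oracle that reads the child's
    # tracts perfectly
    truth[[s]] <- list(sample_id = gen$sample_id,
                       focal_proportion = focal,
                       focal_hap_proportions = hap_props,
                       generations = anc)
  }

  structure(list(sites = sites, genomes = genomes, truth = truth,
                 map = evo$map, config = cfg),
            class = "admix_sim")
}

#' @export
print.admix_sim <- function(x, ...) {
  cat(sprintf(
    "<admix_sim> %d sites on %d chromosomes, %d sampled individuals (g = %d)\n",
    nrow(x$sites), length(unique(x$sites$chrom)), length(x$genomes),
    x$config$g))
  invisible(x)
}
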