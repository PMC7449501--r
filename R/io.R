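# Readers/writers: phased VCF, allele-frequency TSV, HapMap-style
# genetic map, JSON results. Coordinates are 1-based (VCF-native)
# everywhere; the designated "1" allele is the VCF ALT, and
# freqA/freqB refer to ALT.

#' Read phased diploid genomes from a VCF file
#'
#' Accepts biallelic SNP records with phased GT (`0|1` style). By
#' default any unphased (`/`), multiallelic, or malformed record is
#' fatal, with the offending line numbers reported; with
#' `drop_bad = TRUE` such records are dropped and counted.
#'
#' @param path VCF file (uncompressed text).
#' @param drop_bad drop offending records instead of failing.
#' @return List with `genomes` (list of [phased_genome()], one per
#'   sample), `sites` (data.frame chrom/pos/ref/alt), `n_dropped`.
#' @export
read_phased_vcf <- function(path, drop_bad = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("not a VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stop("VCF contains no sample columns")
  samples <- cols[-(1:9)]
  body_idx <- which(seq_along(lines) > hdr & !startsWith(lines, "#") &
                      nzchar(lines))
  n <- length(body_idx)
  if (n == 0L) stop("VCF contains no variant records")
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)

  bad <- character(0)
  keep <- logical(n)
  chrom <- character(n); pos <- integer(n)
  ref <- character(n); alt <- character(n)
  H <- array(NA_integer_, dim = c(n, length(samples), 2L))
  for (i in seq_len(n)) {
    f <- fields[[i]]
    line_no <- body_idx[i]
    if (length(f) < 9L + length(samples)) {
      bad <- c(bad, sprintf("line %d: too few columns", line_no)); next
    }
    if (grepl(",", f[5L], fixed = TRUE)) {
      bad <- c(bad, sprintf("line %d: multiallelic ALT '%s'", line_no, f[5L]))
      next
    }
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) {
      bad <- c(bad, sprintf("line %d: no GT in FORMAT", line_no)); next
    }
    ok <- TRUE
    for (s in seq_along(samples)) {
      gt <- strsplit(f[9L + s], ":", fixed = TRUE)[[1L]][gt_i]
      if (grepl("/", gt, fixed = TRUE)) {
        bad <- c(bad, sprintf("line %d: unphased genotype '%s' (sample %s)",
                              line_no, gt, samples[s]))
        ok <- FALSE; break
      }
      if (!grepl("^[01]\\|[01]$", gt)) {
        bad <- c(bad, sprintf("line %d: malformed genotype '%s' (sample %s)",
                              line_no, gt, samples[s]))
        ok <- FALSE; break
      }
      H[i, s, ] <- as.integer(strsplit(gt, "|", fixed = TRUE)[[1L]])
    }
    if (!ok) next
    keep[i] <- TRUE
    chrom[i] <- f[1L]; pos[i] <- as.integer(f[2L])
    ref[i] <- f[4L]; alt[i] <- f[5L]
  }
  if (length(bad) > 0L && !drop_bad) {
    stop(paste(c("invalid VCF records (use drop_bad = TRUE to drop):",
                 utils::head(bad, 10L)), collapse = "\n  "))
  }
  if (!any(keep)) stop("no usable phased biallelic records in VCF")
  genomes <- lapply(seq_along(samples), function(s) {
    phased_genome(H[keep, s, 1L], H[keep, s, 2L], samples[s])
  })
  names(genomes) <- samples
  list(genomes = genomes,
       sites = data.frame(chrom = chrom[keep], pos = pos[keep],
                          ref = ref[keep], alt = alt[keep],
                          stringsAsFactors = FALSE),
       n_dropped = length(bad))
}

#' Write phased genomes to a VCF file
#'
#' @param genomes a [phased_genome()] or list of them.
#' @param sites a [site_table()] (or data.frame with chrom/pos_bp).
#' @param path output file.
#' @export
write_phased_vcf <- function(genomes, sites, path) {
  if (inherits(genomes, "phased_genome")) genomes <- list(genomes)
  ids <- vapply(genomes, `[[`, character(1), "sample_id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixped",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  gt <- sapply(genomes, function(g) paste0(g$h1, "|", g$h2))
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = length(genomes))
  rows <- paste(sites$chrom, sites$pos_bp, ".", "A", "T", ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Read per-SNP ancestral allele frequencies
#'
#' TSV with columns `chrom, pos, allele, freqA, freqB`; `allele` is
#' the allele the frequencies refer to (matched against the VCF ALT).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_freqs <- function(path) {
  fr <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("chrom", "pos", "allele", "freqA", "freqB")
  if (!all(need %in% names(fr))) {
    stop("frequency table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(fr$freqA < 0 | fr$freqA > 1 | fr$freqB < 0 | fr$freqB > 1)) {
    stop("frequencies must be in [0, 1]")
  }
  fr
}

#' Read a HapMap-style genetic map
#'
#' TSV with columns `chrom, pos, rate, cM` (rate in cM/Mb, `cM`
#' cumulative genetic position). Positions must be sorted within each
#' chromosome.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_genetic_map <- function(path) {
  mp <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("chrom", "pos", "rate", "cM")
  if (!all(need %in% names(mp))) {
    stop("genetic map must have columns: ", paste(need, collapse = ", "))
  }
  for (chr in unique(mp$chrom)) {
    sub <- mp[mp$chrom == chr, ]
    if (is.unsorted(sub$pos, strictly = TRUE) || is.unsorted(sub$cM)) {
      stop(sprintf("genetic map not sorted on chromosome %s", chr))
    }
  }
  mp
}

#' Join VCF sites with frequencies and a genetic map into a site table
#'
#' Sites are matched to the frequency table by (chrom, pos, allele ==
#' ALT); cumulative genetic positions are linearly interpolated from
#' the map. Sites missing a frequency or falling outside the map span
#' are dropped and counted.
#'
#' @param vcf_sites `sites` data.frame from [read_phased_vcf()].
#' @param freqs data.frame from [read_freqs()].
#' @param map data.frame from [read_genetic_map()].
#' @return List with `sites` (a [site_table()]), `keep` (indices of
#'   retained VCF records) and `n_dropped`.
#' @export
build_site_table <- function(vcf_sites, freqs, map) {
  key_v <- paste(vcf_sites$chrom, vcf_sites$pos, vcf_sites$alt)
  key_f <- paste(freqs$chrom, freqs$pos, freqs$allele)
  fi <- match(key_v, key_f)
  in_map <- rep(FALSE, nrow(vcf_sites))
  cM <- rep(NA_real_, nrow(vcf_sites))
  for (chr in unique(vcf_sites$chrom)) {
    vi <- which(vcf_sites$chrom == chr)
    sub <- map[map$chrom == chr, ]
    if (nrow(sub) < 2L) next
    inside <- vcf_sites$pos[vi] >= min(sub$pos) &
      vcf_sites$pos[vi] <= max(sub$pos)
    in_map[vi[inside]] <- TRUE
    cM[vi[inside]] <- approx(sub$pos, sub$cM,
                             xout = vcf_sites$pos[vi[inside]])$y
  }
  keep <- which(!is.na(fi) & in_map)
  if (length(keep) == 0L) {
    stop("no VCF site matches both the frequency table and the genetic map")
  }
  sites <- site_table(chrom = vcf_sites$chrom[keep],
                      pos_bp = vcf_sites$pos[keep],
                      freqA = freqs$freqA[fi[keep]],
                      freqB = freqs$freqB[fi[keep]],
                      cM = cM[keep])
  list(sites = sites, keep = keep,
       n_dropped = nrow(vcf_sites) - length(keep))
}

#' Write a fitted model to JSON
#'
#' @param fit a `fit_result` from [fit_ml()].
#' @param path output JSON path.
#' @param config optional configuration list echoed for provenance.
#' @export
write_fit_json <- function(fit, path, config = NULL) {
  out <- list(K = fit$K, m0_hat = fit$m0_hat,
              rateAB = fit$model_hat$rateAB,
              rateBA = fit$model_hat$rateBA,
              pp = fit$model_hat$pp,
              loglik = fit$loglik, converged = fit$converged,
              n_evals = fit$n_evals, config = config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write simulation truth to JSON
#'
#' @param sim an `admix_sim` from [simulate_admixture()].
#' @param path output JSON path.
#' @param tracts include per-ancestor tract lists.
#' @export
write_truth_json <- function(sim, path, tracts = FALSE) {
  recs <- lapply(sim$truth, function(tr) {
    gens <- lapply(tr$generations, function(g) {
      out <- list(ancestors = g$ancestors, proportions = g$proportions)
      if (tracts) out$tracts <- g$tracts
      out
    })
    list(sample_id = tr$sample_id,
         focal_proportion = tr$focal_proportion,
         focal_hap_proportions = tr$focal_hap_proportions,
         generations = gens)
  })
  jsonlite::write_json(list(individuals = recs), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a site table's frequency and map files
#'
#' Emits the frequency TSV and HapMap-style map TSV corresponding to a
#' simulated site table, in the formats read back by [read_freqs()]
#' and [read_genetic_map()].
#'
#' @param sim an `admix_sim`.
#' @param freq_path,map_path output TSV paths.
#' @export
write_sim_tables <- function(sim, freq_path, map_path) {
  sites <- sim$sites
  data.table::fwrite(data.frame(chrom = sites$chrom, pos = sites$pos_bp,
                                allele = "T", freqA = sites$freqA,
                                freqB = sites$freqB),
                     freq_path, sep = "\t")
  map <- sim$map
  pts <- do.call(rbind, lapply(split(map, map$chrom), function(m) {
    # first point at pos 1 carries its exact cumulative position so
    # linear interpolation reproduces the map
    data.frame(chrom = m$chrom[1L],
               pos = c(1, m$end),
               rate = c(m$rate, m$rate[length(m$rate)]) * 1e8,  # cM/Mb
               cM = c(m$rate[1L], m$cumM_end) * 100)
  }))
  data.table::fwrite(pts, map_path, sep = "\t")
  invisible(c(freq_path, map_path))
}
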