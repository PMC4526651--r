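#' Configuration for the synthetic F1 GBS simulator
#'
#' The generator emulates an outcrossed F1 family genotyped by shallow
#' sequencing: pseudo-testcross (Pt) loci heterozygous in exactly one parent
#' (AB x AA, segregating 1:1 AB:AA, 3:1 alleles), non-Pt loci heterozygous in
#' both parents (AB x AB), meiosis with a no-interference Poisson crossover
#' process, binomial read sampling with per-read miscalls, maximum-likelihood
#' genotype calling with a GATK-style phred GQ, and optional injected
#' anomalies (selfed-mother pollen contaminants; tandem-duplicate loci whose
#' reads collapse into one site).
#'
#' @param n_chrom number of chromosomes
#' @param chrom_length_cM genetic length per chromosome (cM); the expected
#'   crossover count per gamete per chromosome is `chrom_length_cM / 100`
#' @param n_pt_female,n_pt_male Pt loci per chromosome heterozygous in the
#'   mother / father
#' @param n_nonpt loci per chromosome heterozygous in both parents
#' @param n_progeny progeny count
#' @param mean_depth expected reads per call (Poisson), averaged over sites
#' @param depth_sdlog lognormal spread of the per-site tag-depth factor
#'   (mean 1).  GBS tag depth varies over orders of magnitude between
#'   restriction fragments; the default (1.5) spans roughly a 20-fold range
#'   at 95%, so that deep tags saturate the GQ gate while shallow tags show
#'   heterozygote under-calling.  Set 0 for flat coverage.
#' @param seq_error per-read miscall probability
#' @param n_contaminants selfed-mother progeny to inject
#' @param n_dup_loci Pt loci collapsed with an invariant duplicate copy
#' @param seed RNG seed (integer); each stage derives its own substream
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_chrom = 19, chrom_length_cM = 100,
                       n_pt_female = 55, n_pt_male = 55, n_nonpt = 10,
                       n_progeny = 200, mean_depth = 6, depth_sdlog = 1.5,
                       seq_error = 0.01,
                       n_contaminants = 0, n_dup_loci = 0, seed = 1) {
  cfg <- list(n_chrom = n_chrom, chrom_length_cM = chrom_length_cM,
              n_pt_female = n_pt_female, n_pt_male = n_pt_male,
              n_nonpt = n_nonpt, n_progeny = n_progeny,
              mean_depth = mean_depth, depth_sdlog = depth_sdlog,
              seq_error = seq_error,
              n_contaminants = n_contaminants, n_dup_loci = n_dup_loci,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chrom >= 1, chrom_length_cM > 0, n_pt_female >= 0,
              n_pt_male >= 0, n_nonpt >= 0, n_progeny >= 1, mean_depth > 0,
              depth_sdlog >= 0,
              seq_error >= 0, seq_error < 0.5, n_contaminants >= 0,
              n_dup_loci >= 0)
  })
  if (cfg$n_contaminants >= cfg$n_progeny)
    stop("n_contaminants must be smaller than n_progeny")
  structure(cfg, class = "sim_config")
}

BP_PER_CM <- 2.5e5  # physical scale used for simulated coordinates

# inherited haplotype (0/1) of one gamete at sorted positions, under a
# Poisson crossover process with no interference
.gamete_phase <- function(pos_cM, length_cM) {
  start <- sample(0:1, 1)
  nxo <- stats::rpois(1, length_cM / 100)
  if (nxo == 0) return(rep.int(start, length(pos_cM)))
  xo <- sort(stats::runif(nxo, 0, length_cM))
  (start + findInterval(pos_cM, xo)) %% 2L
}

#' Simulate true genotypes of an F1 family
#'
#' Draws marker positions, assigns each Pt locus a heterozygous (informative)
#' parent and a carrier haplotype (phase) for its minor allele, simulates one
#' maternal and one paternal gamete per progeny per chromosome, and returns
#' the true genotype matrix (progeny plus both parents) together with the
#' truth set used by downstream tests.
#'
#' @param config sim_config
#' @return list with `genotypes` (genotype_matrix of true calls, GQ 99) and
#'   `truth` (list: `markers` data.frame with type/parent/phases/true LG,
#'   `hap_mother`/`hap_father` inherited-haplotype matrices sites x progeny,
#'   `contaminants`, `duplicates`)
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  per_chrom <- config$n_pt_female + config$n_pt_male + config$n_nonpt
  chroms <- rep(seq_len(config$n_chrom), each = per_chrom)
  pos_cM <- unlist(lapply(seq_len(config$n_chrom), function(cc)
    sort(stats::runif(per_chrom, 0, config$chrom_length_cM))))
  type <- unlist(lapply(seq_len(config$n_chrom), function(cc)
    sample(rep(c("pt_female", "pt_male", "nonpt"),
               c(config$n_pt_female, config$n_pt_male, config$n_nonpt)))))
  n_s <- length(chroms)
  pos_bp <- as.integer(round(pos_cM * BP_PER_CM)) + 1L
  while (any(d <- duplicated(paste(chroms, pos_bp)))) pos_bp[d] <- pos_bp[d] + 1L

  phase_f <- ifelse(type %in% c("pt_female", "nonpt"), sample(0:1, n_s, TRUE), NA)
  phase_m <- ifelse(type %in% c("pt_male", "nonpt"), sample(0:1, n_s, TRUE), NA)

  n_p <- config$n_progeny
  hap_mother <- hap_father <- matrix(NA_integer_, n_s, n_p)
  for (p in seq_len(n_p)) {
    for (cc in seq_len(config$n_chrom)) {
      i <- which(chroms == cc)
      hap_mother[i, p] <- .gamete_phase(pos_cM[i], config$chrom_length_cM)
      hap_father[i, p] <- .gamete_phase(pos_cM[i], config$chrom_length_cM)
    }
  }
  carry_f <- !is.na(phase_f) & hap_mother == phase_f  # maternal gamete has minor
  carry_m <- !is.na(phase_m) & hap_father == phase_m
  gt_prog <- carry_f + carry_m
  gt_mother <- ifelse(is.na(phase_f), 0L, 1L)
  gt_father <- ifelse(is.na(phase_m), 0L, 1L)

  sites <- data.frame(chrom = as.character(chroms), pos = pos_bp,
                      major = "A", minor = "B")
  samples <- data.frame(id = c(sprintf("P%03d", seq_len(n_p)), "mother", "father"),
                        role = c(rep("progeny", n_p), "mother", "father"))
  gt <- cbind(gt_prog, gt_mother, gt_father)
  storage.mode(gt) <- "integer"
  gm <- genotype_matrix(sites, samples, gt, gq = matrix(99L, n_s, n_p + 2))
  truth <- list(markers = data.frame(site_id = gm$sites$site_id,
                                     chrom = sites$chrom, pos = pos_bp,
                                     pos_cM = pos_cM, type = type,
                                     parent = c(pt_female = "female", pt_male = "male",
                                                nonpt = "both")[type],
                                     phase_female = phase_f, phase_male = phase_m,
                                     true_lg = ifelse(type == "nonpt", NA,
                                                      paste0("chr", chroms, "_",
                                                             ifelse(type == "pt_female",
                                                                    "female", "male"))),
                                     row.names = NULL),
                hap_mother = hap_mother, hap_father = hap_father,
                contaminants = character(0), duplicates = character(0))
  list(genotypes = gm, truth = truth)
}

# termwise a*log(b) with the 0*log(0) = 0 convention (exact noiseless limit)
.xlog <- function(a, logb) ifelse(a == 0, 0, a * logb)

# ML genotype call + phred GQ from (minor reads k, depth n)
.call_from_reads <- function(k, n, e) {
  l_aa <- .xlog(k, log(e)) + .xlog(n - k, log(1 - e))
  l_ab <- n * log(0.5)
  l_bb <- .xlog(k, log(1 - e)) + .xlog(n - k, log(e))
  L <- cbind(l_aa, l_ab, l_bb)
  call <- max.col(L, ties.method = "first") - 1L
  best <- L[cbind(seq_len(nrow(L)), call + 1L)]
  L[cbind(seq_len(nrow(L)), call + 1L)] <- -Inf
  second <- pmax(L[, 1], L[, 2], L[, 3])
  gq <- pmin(99, round(10 * (best - second) / log(10)))
  gq[!is.finite(gq)] <- 99
  gq <- as.integer(gq)
  miss <- n == 0L
  call[miss] <- NA_integer_
  gq[miss] <- 0L
  list(gt = call, gq = gq)
}

# per-site tag-depth factors (mean 1), reproducible from the config alone;
# seeds the RNG at seed + 1 and consumes exactly n_sites draws when dispersed
.site_depth_weights <- function(n_sites, config) {
  set.seed(config$seed + 1L)
  if (config$depth_sdlog <= 0) return(rep(1, n_sites))
  exp(stats::rnorm(n_sites, -config$depth_sdlog^2 / 2, config$depth_sdlog))
}

#' Simulate GBS sequencing and genotype calling
#'
#' Per call: read depth ~ Poisson(`mean_depth` times the site's tag-depth
#' factor, see `depth_sdlog`); each read reports the minor
#' allele with probability `seq_error` (true AA), `0.5` (AB) or
#' `1 - seq_error` (BB); the called genotype maximises the binomial
#' likelihood under a uniform genotype prior, and GQ is the phred-scaled gap
#' between the best and second-best genotype log-likelihood, capped at 99.
#' Zero depth yields a missing call with GQ 0.
#'
#' @param truth_gm genotype_matrix of true genotypes (no missing calls)
#' @param config sim_config
#' @return genotype_matrix of called genotypes with AD and GQ filled
#' @export
simulate_sequencing <- function(truth_gm, config) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(truth_gm$gt)) stop("truth genotypes must not be missing")
  w <- .site_depth_weights(nrow(truth_gm$sites), config)
  g <- as.vector(truth_gm$gt)
  e <- config$seq_error
  n <- stats::rpois(length(g), rep(config$mean_depth * w,
                                   nrow(truth_gm$samples)))
  k <- stats::rbinom(length(g), n, c(e, 0.5, 1 - e)[g + 1L])
  cl <- .call_from_reads(k, n, e)
  d <- dim(truth_gm$gt)
  genotype_matrix(truth_gm$sites, truth_gm$samples,
                  matrix(cl$gt, d[1], d[2]), matrix(cl$gq, d[1], d[2]),
                  matrix(as.integer(n - k), d[1], d[2]),
                  matrix(as.integer(k), d[1], d[2]))
}

#' Inject pollen contaminants and collapsed tandem-duplicate loci
#'
#' Contaminants are regenerated as selfed offspring of the mother (the
#' dominant contamination mode in practice): a new pair of maternal gametes
#' replaces the true parental contribution and the affected columns are
#' re-sequenced.  Duplicate loci pool the reads of a Pt site with an
#' invariant homozygous-major duplicate copy sequenced at the same expected
#' depth, then re-call genotypes from the pooled counts, halving the
#' minor-read fraction (pooled expectation 1/8 instead of 1/4).
#'
#' @param calls genotype_matrix of called genotypes (from
#'   [simulate_sequencing()])
#' @param truth truth set from [simulate_family()]
#' @param config sim_config
#' @return list with updated `calls` and `truth` (contaminant ids and
#'   duplicate site ids filled in)
#' @export
inject_anomalies <- function(calls, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_contaminants >= config$n_progeny)
    stop("n_contaminants must be smaller than n_progeny")
  if (config$n_contaminants == 0 && config$n_dup_loci == 0)
    return(list(calls = calls, truth = truth))
  w <- .site_depth_weights(nrow(calls$sites), config)
  set.seed(config$seed + 2L)
  e <- config$seq_error
  prog <- which(calls$samples$role == "progeny")
  mk <- truth$markers
  n_s <- nrow(mk)

  if (config$n_contaminants > 0) {
    who <- sample(prog, config$n_contaminants)
    for (j in who) {
      gt_self <- integer(n_s)
      for (cc in unique(mk$chrom)) {
        i <- which(mk$chrom == cc)
        g1 <- .gamete_phase(mk$pos_cM[i], config$chrom_length_cM)
        g2 <- .gamete_phase(mk$pos_cM[i], config$chrom_length_cM)
        c1 <- !is.na(mk$phase_female[i]) & g1 == mk$phase_female[i]
        c2 <- !is.na(mk$phase_female[i]) & g2 == mk$phase_female[i]
        gt_self[i] <- c1 + c2
      }
      n <- stats::rpois(n_s, config$mean_depth * w)
      k <- stats::rbinom(n_s, n, c(e, 0.5, 1 - e)[gt_self + 1L])
      cl <- .call_from_reads(k, n, e)
      calls$gt[, j] <- cl$gt
      calls$gq[, j] <- cl$gq
      calls$ad_major[, j] <- as.integer(n - k)
      calls$ad_minor[, j] <- as.integer(k)
      truth$hap_mother[, j] <- NA_integer_
      truth$hap_father[, j] <- NA_integer_
    }
    truth$contaminants <- calls$samples$id[who]
  }

  if (config$n_dup_loci > 0) {
    pt <- which(mk$type %in% c("pt_female", "pt_male"))
    dup <- sample(pt, min(config$n_dup_loci, length(pt)))
    cols <- seq_len(nrow(calls$samples))
    for (i in dup) {
      n2 <- stats::rpois(length(cols), config$mean_depth * w[i])
      k2 <- stats::rbinom(length(cols), n2, e)  # duplicate copy is invariant AA
      k <- calls$ad_minor[i, cols] + k2
      n <- calls$ad_major[i, cols] + calls$ad_minor[i, cols] + n2
      cl <- .call_from_reads(k, n, e)
      calls$gt[i, cols] <- cl$gt
      calls$gq[i, cols] <- cl$gq
      calls$ad_major[i, cols] <- as.integer(n - k)
      calls$ad_minor[i, cols] <- as.integer(k)
    }
    truth$duplicates <- mk$site_id[dup]
  }
  list(calls = calls, truth = truth)
}

#' One-call simulation of a full synthetic GBS family
#'
#' Convenience wrapper: [simulate_family()] then [simulate_sequencing()] then
#' [inject_anomalies()].  Bit-reproducible for a fixed config.
#'
#' @param config sim_config
#' @return list with `truth_genotypes`, `calls`, `truth`
#' @export
simulate_gbs_family <- function(config) {
  fam <- simulate_family(config)
  calls <- simulate_sequencing(fam$genotypes, config)
  an <- inject_anomalies(calls, fam$truth, config)
  list(truth_genotypes = fam$genotypes, calls = an$calls, truth = an$truth)
}

#' Expected pooled minor-tag frequency at a pseudo-testcross site
#'
#' Under the AB x AA model, half the progeny carry the minor allele; within a
#' carrier the minor allele sits on 1 of the `2 * n_copies` collapsed
#' haplotype copies sequenced at the site (n_copies = 1 for a normal locus,
#' 2 when the tag collapses two tandem-duplicated regions).  Pooling read
#' depth across progeny, the expected minor-read fraction is
#' `1 / (4 * n_copies)`: 0.25 for a normal Pt site, 0.125 for a two-copy
#' collapse (the 1:7 segregation signature).
#'
#' @param n_copies number of collapsed genomic copies (>= 1)
#' @return expected pooled minor-read fraction
#' @export
expected_mtf <- function(n_copies = 1) {
  stopifnot(n_copies >= 1)
  0.5 * 1 / (2 * n_copies)
}

#' Simulate phase-encoded binary genotypes for one linkage group
#'
#' Direct generator used for ordering/curation studies: markers at fixed cM
#' spacing on one parental LG, inherited haplotype following a Markov chain
#' with Haldane switch probabilities (no interference), observed values
#' flipped independently with probability `epsilon` and missing at
#' `missing_rate`.
#'
#' @param n_markers markers on the LG
#' @param n_progeny progeny
#' @param spacing_cM distance between adjacent markers (cM)
#' @param epsilon per-call flip (genotyping error) probability
#' @param missing_rate per-call missing probability
#' @param seed RNG seed
#' @return list with `values` (markers x progeny 0/1/NA), `truth`
#'   (error-free haplotypes), `pos_cM`
#' @export
simulate_lg_binary <- function(n_markers, n_progeny, spacing_cM = 2,
                               epsilon = 0, missing_rate = 0, seed = 1) {
  set.seed(as.integer(seed))
  r <- 0.5 * (1 - exp(-2 * spacing_cM / 100))
  truth <- matrix(NA_integer_, n_markers, n_progeny)
  truth[1, ] <- sample(0:1, n_progeny, TRUE)
  for (i in seq_len(n_markers - 1)) {
    flip <- stats::rbinom(n_progeny, 1, r)
    truth[i + 1, ] <- (truth[i, ] + flip) %% 2L
  }
  obs <- truth
  if (epsilon > 0) {
    fl <- matrix(stats::rbinom(length(obs), 1, epsilon), n_markers)
    obs <- (obs + fl) %% 2L
  }
  if (missing_rate > 0)
    obs[matrix(stats::runif(length(obs)) < missing_rate, n_markers)] <- NA_integer_
  rownames(obs) <- rownames(truth) <- sprintf("M%03d", seq_len(n_markers))
  list(values = obs, truth = truth, pos_cM = (seq_len(n_markers) - 1) * spacing_cM)
}

#' Flip binary genotype calls at a fixed error rate
#'
#' Utility for planting uniform genotyping error into a binary marker matrix
#' (missing calls are left missing).
#'
#' @param bm binary_markers
#' @param rate flip probability per non-missing call
#' @param seed RNG seed
#' @return binary_markers with flipped calls
#' @export
binary_inject_errors <- function(bm, rate, seed = 1) {
  set.seed(as.integer(seed))
  v <- bm$values
  fl <- matrix(stats::runif(length(v)) < rate, nrow(v))
  v[fl & !is.na(v)] <- 1L - v[fl & !is.na(v)]
  bm$values <- v
  bm
}
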