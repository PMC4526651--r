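#' Parameters for pseudo-testcross marker identification
#'
#' Thresholds of the parent-independent Pt selection and error-correction
#' stage.  Defaults follow the published pipeline: alleles under 5%
#' frequency are erased as putative sequencing errors, sites need a 50%
#' genotyping rate, candidate sites must show a minor allele frequency of
#' 0.25 +/- 0.125 (and major 0.75 -/+ 0.125) with at least two genotypes at
#' or above 5% frequency, the GQ gate sits at 98, and post-correction sites
#' with over 5% high-quality BB calls are rejected as high error.
#'
#' @param allele_freq_min minimum allele frequency (alleles below are erased)
#' @param genotype_rate_min minimum per-site call rate
#' @param maf_center,maf_halfwidth acceptance band for the minor allele
#'   frequency (closed interval)
#' @param major_center acceptance centre for the major allele frequency
#' @param gq_threshold phred GQ at or above which a call counts as high
#'   quality
#' @param site_error_max maximum fraction of high-quality BB calls per site
#' @param genotype_freq_min minimum genotype-class frequency to count as
#'   segregating
#' @return list of class `pt_params`
#' @export
pt_params <- function(allele_freq_min = 0.05, genotype_rate_min = 0.5,
                      maf_center = 0.25, maf_halfwidth = 0.125,
                      major_center = 0.75, gq_threshold = 98,
                      site_error_max = 0.05, genotype_freq_min = 0.05) {
  p <- list(allele_freq_min = allele_freq_min,
            genotype_rate_min = genotype_rate_min,
            maf_center = maf_center, maf_halfwidth = maf_halfwidth,
            major_center = major_center, gq_threshold = gq_threshold,
            site_error_max = site_error_max,
            genotype_freq_min = genotype_freq_min)
  stopifnot(p$allele_freq_min > 0, p$allele_freq_min <= 1,
            p$genotype_rate_min > 0, p$genotype_rate_min <= 1,
            p$gq_threshold >= 0, p$gq_threshold <= 99)
  structure(p, class = "pt_params")
}

# minor allele frequency per site over non-missing calls of a dosage matrix
.maf_of <- function(g) rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))

#' Prefilter sites: erase rare alleles, drop low-rate and monomorphic sites
#'
#' Alleles with frequency below `allele_freq_min` (allele-copy denominator)
#' are erased: calls homozygous for an erased allele become missing and
#' heterozygous calls keep their retained allele.  Sites with a call rate
#' below `genotype_rate_min` are then removed, and sites left monomorphic by
#' the erasure are removed and counted separately.
#'
#' @param gm genotype_matrix restricted to progeny
#' @param params pt_params
#' @return list with `genotypes` (filtered genotype_matrix) and `audit`
#'   (counts: initial, low_rate, monomorphic)
#' @export
prefilter_sites <- function(gm, params = pt_params()) {
  if (!length(progeny_cols(gm))) stop("no progeny samples")
  gm <- progeny_genotypes(gm)
  g <- gm$gt
  maf <- .maf_of(g)
  erase_minor <- !is.na(maf) & maf < params$allele_freq_min & maf > 0
  erase_major <- !is.na(maf) & (1 - maf) < params$allele_freq_min
  for (i in which(erase_minor)) {
    gi <- g[i, ]
    gi[!is.na(gi) & gi == GT_BB] <- NA_integer_  # only the erased allele
    gi[!is.na(gi) & gi == GT_AB] <- GT_AA        # retained major kept
    g[i, ] <- gi
  }
  for (i in which(erase_major)) {
    gi <- g[i, ]
    gi[!is.na(gi) & gi == GT_AA] <- NA_integer_
    gi[!is.na(gi) & gi == GT_AB] <- GT_BB
    g[i, ] <- gi
  }
  gm$gt <- g
  rate <- rowMeans(!is.na(g))
  low_rate <- rate < params$genotype_rate_min
  n_levels <- vapply(seq_len(nrow(g)),
                     function(i) length(unique(g[i, !is.na(g[i, ])])), 0L)
  mono <- !low_rate & n_levels < 2L
  keep <- !low_rate & !mono
  list(genotypes = subset_genotypes(gm, sites = which(keep)),
       audit = c(initial = nrow(gm$sites), low_rate = sum(low_rate),
                 monomorphic = sum(mono)))
}

#' Select candidate pseudo-testcross sites by segregation pattern
#'
#' Retains sites with two segregating alleles of frequency at or above
#' `allele_freq_min`, two or more genotype classes of frequency at or above
#' `genotype_freq_min`, minor allele frequency within
#' `maf_center +/- maf_halfwidth` (closed interval) and major allele
#' frequency within the complementary band — the 3:1 allele / 1:1 genotype
#' signature of an AB x AA cross.  All frequencies are computed over
#' non-missing progeny calls.
#'
#' @param gm prefiltered genotype_matrix (progeny only)
#' @param params pt_params
#' @return list with `genotypes` (candidate sites) and `audit`
#'   (bad_segregation count)
#' @export
select_candidate_sites <- function(gm, params = pt_params()) {
  g <- gm$gt[, progeny_cols(gm), drop = FALSE]
  n_called <- rowSums(!is.na(g))
  maf <- .maf_of(g)
  lo <- params$maf_center - params$maf_halfwidth
  hi <- params$maf_center + params$maf_halfwidth
  maj <- 1 - maf
  maj_lo <- params$major_center - params$maf_halfwidth
  maj_hi <- params$major_center + params$maf_halfwidth
  gfreq_ok <- vapply(seq_len(nrow(g)), function(i) {
    tab <- tabulate(g[i, ] + 1L, 3L) / n_called[i]
    sum(tab >= params$genotype_freq_min) >= 2L
  }, TRUE)
  ok <- n_called > 0 &
    pmin(maf, maj) >= params$allele_freq_min &
    maf >= lo & maf <= hi & maj >= maj_lo & maj <= maj_hi &
    gfreq_ok
  list(genotypes = subset_genotypes(gm, sites = which(ok)),
       audit = c(bad_segregation = sum(!ok)))
}

#' Apply the GQ-driven pseudo-testcross genotype correction rules
#'
#' Per call at a candidate Pt site: (1) AA with GQ below the threshold is
#' converted to missing and flagged masked (potentially an under-sampled
#' heterozygote); (2) BB with GQ at or above the threshold is converted to
#' missing and flagged error (impossible at a Pt site); (3) BB with GQ below
#' the threshold is assumed an under-sampled heterozygote, converted to AB
#' and flagged corrected.  AB calls and high-quality AA calls are untouched.
#'
#' @param gm candidate-site genotype_matrix (progeny only)
#' @param params pt_params
#' @return genotype_matrix with corrected calls and flags
#' @export
correct_pt_genotypes <- function(gm, params = pt_params()) {
  g <- gm$gt; q <- gm$gq; f <- gm$flag
  thr <- params$gq_threshold
  masked <- !is.na(g) & g == GT_AA & q < thr
  err <- !is.na(g) & g == GT_BB & q >= thr
  corr <- !is.na(g) & g == GT_BB & q < thr
  g[masked] <- NA_integer_; f[masked] <- FLAG_MASKED
  g[err] <- NA_integer_;    f[err] <- FLAG_ERROR
  g[corr] <- GT_AB;         f[corr] <- FLAG_CORRECTED
  gm$gt <- g; gm$flag <- f
  gm
}

#' Identify pseudo-testcross markers from progeny segregation
#'
#' Orchestrates the full parent-independent stage: prefilter, candidate
#' selection, GQ-driven correction, then a final curation removing sites
#' whose post-correction call rate falls below `genotype_rate_min` or whose
#' error rate — the fraction of high-quality BB calls among pre-correction
#' non-missing calls — exceeds `site_error_max`.  Parental/grandparental
#' genotypes, when present, are never used for selection; their high-quality
#' calls at retained loci are reported for validation.
#'
#' @param gm genotype_matrix (progeny plus optional progenitors)
#' @param params pt_params
#' @return list with `genotypes` (retained Pt markers, corrected, progeny
#'   only), `binary` (binary_markers), `audit` (named stage counts summing
#'   to the initial site count), `site_stats` (per retained site: fraction
#'   masked / corrected / error), `progenitors` (high-GQ progenitor dosages
#'   at retained loci, or NULL)
#' @export
identify_pt_markers <- function(gm, params = pt_params()) {
  progenitor_idx <- which(gm$samples$role != "progeny")
  pre <- prefilter_sites(gm, params)
  cand <- select_candidate_sites(pre$genotypes, params)
  pre_correction <- cand$genotypes
  corrected <- correct_pt_genotypes(pre_correction, params)

  g <- corrected$gt
  rate <- rowMeans(!is.na(g))
  n_precall <- rowSums(!is.na(pre_correction$gt))
  err_frac <- rowSums(corrected$flag == FLAG_ERROR) / pmax(n_precall, 1L)
  low_rate2 <- rate < params$genotype_rate_min
  high_err <- !low_rate2 & err_frac > params$site_error_max
  keep <- !low_rate2 & !high_err

  out <- subset_genotypes(corrected, sites = which(keep))
  audit <- c(pre$audit, cand$audit,
             low_rate_after_correction = sum(low_rate2),
             high_error = sum(high_err), retained = sum(keep))
  site_stats <- data.frame(
    site_id = out$sites$site_id,
    maf_precorrection = .maf_of(pre_correction$gt[keep, , drop = FALSE]),
    frac_masked = rowMeans(out$flag == FLAG_MASKED),
    frac_corrected = rowMeans(out$flag == FLAG_CORRECTED),
    frac_error = err_frac[keep], row.names = NULL)

  progenitors <- NULL
  if (length(progenitor_idx)) {
    pg <- subset_genotypes(gm, sites = match(out$sites$site_id, gm$sites$site_id),
                           samples = progenitor_idx)
    pgt <- pg$gt
    pgt[pg$gq < params$gq_threshold] <- NA_integer_
    progenitors <- as.data.frame(pgt)
    names(progenitors) <- pg$samples$id
    progenitors <- cbind(data.frame(site_id = pg$sites$site_id), progenitors)
  }
  list(genotypes = out, binary = to_binary(out), audit = audit,
       site_stats = site_stats, progenitors = progenitors)
}

#' Write the Pt identification audit as a TSV of stage counts
#' @param audit named vector from [identify_pt_markers()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pt_audit <- function(audit, path) {
  utils::write.table(data.frame(stage = names(audit), n = as.integer(audit)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
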