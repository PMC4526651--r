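#' Yang-type genetic relatedness between samples
#'
#' For samples j, k the statistic is the mean over usable sites of
#' `(g_j - 2p)(g_k - 2p) / (2p(1-p))`, with g the minor-allele dosage (0/1/2)
#' and p the minor allele frequency computed across all samples at that site.
#' A site is usable for a pair when both calls are non-missing with GQ at or
#' above `gq_min` and p is strictly between 0 and 1.  Unrelated samples
#' score near 0; a parent-offspring pair scores higher.  Symmetric in its
#' two arguments.
#'
#' @param gm genotype_matrix
#' @param ids_a,ids_b sample ids (statistics computed for every a x b pair)
#' @param gq_min minimum genotype quality for a call to be used
#' @return numeric matrix length(ids_a) x length(ids_b); NA when a pair has
#'   no usable site
#' @export
relatedness_pairs <- function(gm, ids_a, ids_b, gq_min = 98) {
  ia <- match(ids_a, gm$samples$id); ib <- match(ids_b, gm$samples$id)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample ids")
  ok <- !is.na(gm$gt) & gm$gq >= gq_min
  g <- gm$gt
  p <- rowSums(ifelse(ok, g, 0L)) / (2 * rowSums(ok))
  use_site <- is.finite(p) & p > 0 & p < 1
  denom <- 2 * p * (1 - p)
  out <- matrix(NA_real_, length(ia), length(ib), dimnames = list(ids_a, ids_b))
  for (x in seq_along(ia)) for (y in seq_along(ib)) {
    j <- ia[x]; k <- ib[y]
    u <- use_site & ok[, j] & ok[, k]
    if (!any(u)) next
    out[x, y] <- mean((g[u, j] - 2 * p[u]) * (g[u, k] - 2 * p[u]) / denom[u])
  }
  out
}

#' Relatedness of each progeny to each parent
#'
#' @param gm genotype_matrix containing samples with roles mother and father
#' @param gq_min minimum genotype quality
#' @return data.frame with progeny id, rel_mother, rel_father
#' @export
relatedness_matrix <- function(gm, gq_min = 98) {
  mo <- gm$samples$id[gm$samples$role == "mother"]
  fa <- gm$samples$id[gm$samples$role == "father"]
  if (!length(mo) || !length(fa)) stop("both parents must be present")
  prog <- gm$samples$id[gm$samples$role == "progeny"]
  r <- relatedness_pairs(gm, prog, c(mo, fa), gq_min = gq_min)
  data.frame(id = prog, rel_mother = r[, 1], rel_father = r[, 2],
             row.names = NULL)
}

#' Per-progeny Mendelian incompatibility counts against each parent
#'
#' A progeny call increments the male-incompatible count when it carries an
#' allele with zero copies in the father's genotype at that site, and
#' likewise for the mother; one call can increment both.  Only calls with
#' GQ at or above `gq_min` enter the counts (matching the quality filter
#' applied before the relatedness statistic); sites where either parent is
#' missing or low-quality, and missing/low-quality progeny calls, are
#' skipped.  For true progeny the two counts are comparable and small;
#' selfed or contaminant progeny show a strong male excess.
#'
#' @param gm genotype_matrix with both parents present
#' @param gq_min minimum genotype quality for a call to be counted
#' @return data.frame with id, n_male_incompatible, n_female_incompatible
#' @export
mendelian_incompatibilities <- function(gm, gq_min = 98) {
  mo <- which(gm$samples$role == "mother")
  fa <- which(gm$samples$role == "father")
  if (!length(mo) || !length(fa)) stop("both parents must be present")
  prog <- which(gm$samples$role == "progeny")
  hq <- gm$gq >= gq_min
  gmo <- gm$gt[, mo]; gfa <- gm$gt[, fa]
  site_ok <- !is.na(gmo) & !is.na(gfa) & hq[, mo] & hq[, fa]
  # incompatibility of a progeny dosage with one parental dosage
  incomp_with <- function(gp, gpar) {
    # progeny carries major (gp<2) but parent has no major (gpar==2), or
    # progeny carries minor (gp>0) but parent has no minor (gpar==0)
    (gp < 2L & gpar == 2L) | (gp > 0L & gpar == 0L)
  }
  res <- t(vapply(prog, function(j) {
    gp <- gm$gt[, j]
    u <- site_ok & !is.na(gp) & hq[, j]
    c(male = sum(incomp_with(gp[u], gfa[u])),
      female = sum(incomp_with(gp[u], gmo[u])))
  }, c(male = 0, female = 0)))
  data.frame(id = gm$samples$id[prog],
             n_male_incompatible = as.integer(res[, "male"]),
             n_female_incompatible = as.integer(res[, "female"]),
             row.names = NULL)
}

#' Flag suspect progeny (contaminants, selfs, mislabels)
#'
#' Combines two automated rules mirroring the usual visual inspection:
#' relatedness outliers deviate from the progeny median relatedness to either
#' parent by more than `rel_mad_k` median absolute deviations; Mendelian
#' outliers have a male/female incompatibility ratio (computed as
#' `(male + 1) / (female + 1)`) of at least `ratio_min` with a
#' male-incompatible count above the progeny median.  A progeny is flagged
#' only when both rules agree (their intersection).
#'
#' @param relatedness output of [relatedness_matrix()]
#' @param mendel output of [mendelian_incompatibilities()]
#' @param rel_mad_k MAD multiplier for the relatedness rule
#' @param ratio_min minimum male/female incompatibility ratio
#' @return data.frame (one row per progeny) with the statistics, the two
#'   rule outcomes, `flagged` and `reason`; attribute `"auto"` is FALSE when
#'   fewer than 10 progeny prevented automatic flagging
#' @export
flag_suspect_progeny <- function(relatedness, mendel, rel_mad_k = 4,
                                 ratio_min = 3) {
  stopifnot(identical(relatedness$id, mendel$id))
  rep <- data.frame(id = relatedness$id,
                    rel_mother = relatedness$rel_mother,
                    rel_father = relatedness$rel_father,
                    n_male_incompatible = mendel$n_male_incompatible,
                    n_female_incompatible = mendel$n_female_incompatible)
  rep$incompat_ratio <- (rep$n_male_incompatible + 1) /
    (rep$n_female_incompatible + 1)
  n <- nrow(rep)
  mad_dev <- function(x) {
    m <- stats::median(x, na.rm = TRUE)
    s <- max(stats::mad(x, na.rm = TRUE), 1e-8)
    abs(x - m) / s
  }
  rel_out <- mad_dev(rep$rel_mother) > rel_mad_k |
    mad_dev(rep$rel_father) > rel_mad_k
  rel_out[is.na(rel_out)] <- FALSE
  med_male <- stats::median(rep$n_male_incompatible)
  men_out <- rep$incompat_ratio >= ratio_min & rep$n_male_incompatible > med_male
  if (n < 10) {
    warning("fewer than 10 progeny: reporting statistics without automatic flags")
    rep$relatedness_outlier <- rel_out
    rep$mendelian_outlier <- men_out
    rep$flagged <- FALSE
    rep$reason <- ""
    attr(rep, "auto") <- FALSE
    return(rep)
  }
  rep$relatedness_outlier <- rel_out
  rep$mendelian_outlier <- men_out
  rep$flagged <- rel_out & men_out
  rep$reason <- ifelse(rep$flagged, "both",
                       ifelse(rel_out, "relatedness",
                              ifelse(men_out, "mendelian", "")))
  attr(rep, "auto") <- TRUE
  rep
}

#' Remove samples and drop sites left uninformative
#'
#' After removing flagged samples, sites that are invariant or entirely
#' missing among the remaining progeny are dropped.
#'
#' @param gm genotype_matrix
#' @param remove_ids sample ids to remove
#' @return genotype_matrix
#' @export
remove_flagged_samples <- function(gm, remove_ids) {
  keep <- !(gm$samples$id %in% remove_ids)
  gm2 <- subset_genotypes(gm, samples = which(keep))
  g <- gm2$gt[, progeny_cols(gm2), drop = FALSE]
  n_called <- rowSums(!is.na(g))
  n_lv <- vapply(seq_len(nrow(g)), function(i) length(unique(g[i, !is.na(g[i, ])])), 0L)
  subset_genotypes(gm2, sites = which(n_called > 0 & n_lv > 1))
}
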