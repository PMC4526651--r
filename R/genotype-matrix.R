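#' Genotype codes
#'
#' Genotypes are stored as integer dosages of the minor (B) allele relative to
#' the site's major/minor assignment: 0 = AA, 1 = AB, 2 = BB, `NA` = missing.
#' Per-call flags record the error-correction state: `"N"` none, `"M"` masked,
#' `"E"` error, `"C"` corrected (corrected calls are always AB).
#'
#' @name genotype-codes
#' @keywords internal
NULL

GT_AA <- 0L
GT_AB <- 1L
GT_BB <- 2L

FLAG_NONE <- "N"
FLAG_MASKED <- "M"
FLAG_ERROR <- "E"
FLAG_CORRECTED <- "C"

#' Construct a sites-by-samples genotype call matrix
#'
#' The central container of the pipeline: a table of biallelic sites
#' (major/minor allele convention), a sample sheet with family roles, and
#' aligned per-call matrices of genotype, genotype quality, allele depths and
#' correction flags.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp),
#'   `major`, `minor` (allele symbols) and optionally `site_id`; when absent,
#'   site ids are built as `S{chrom}_{pos}`.
#' @param samples data.frame with columns `id` and `role`, role one of
#'   `"progeny"`, `"mother"`, `"father"`, `"grandparent"`.
#' @param gt integer matrix (sites x samples) of minor-allele dosages
#'   0/1/2 with `NA` for missing.
#' @param gq integer matrix of phred-scaled genotype qualities (>= 0);
#'   missing GQ must be encoded as 0, not `NA`.
#' @param ad_major,ad_minor integer matrices of per-allele read depths.
#' @param flag character matrix of correction flags ("N","M","E","C").
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, gt, gq = NULL,
                            ad_major = NULL, ad_minor = NULL, flag = NULL) {
  sites <- as.data.frame(sites)
  samples <- as.data.frame(samples)
  stopifnot(all(c("chrom", "pos", "major", "minor") %in% names(sites)),
            all(c("id", "role") %in% names(samples)))
  if (is.null(sites$site_id))
    sites$site_id <- paste0("S", sites$chrom, "_", sites$pos)
  if (anyDuplicated(sites$site_id))
    stop("site ids are not unique")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  if (any(sites$major == sites$minor))
    stop("major and minor alleles must differ")
  bad_role <- setdiff(samples$role, c("progeny", "mother", "father", "grandparent"))
  if (length(bad_role)) stop("unknown sample role: ", paste(bad_role, collapse = ", "))
  if (sum(samples$role == "mother") > 1 || sum(samples$role == "father") > 1)
    stop("at most one mother and one father allowed")
  n_s <- nrow(sites); n_i <- nrow(samples)
  gt <- as.matrix(gt)
  if (!all(dim(gt) == c(n_s, n_i)))
    stop("gt dimensions do not match sites x samples")
  storage.mode(gt) <- "integer"
  if (any(gt[!is.na(gt)] < 0L | gt[!is.na(gt)] > 2L))
    stop("gt values must be 0, 1, 2 or NA")
  fill <- function(x, default, mode) {
    if (is.null(x)) x <- matrix(default, n_s, n_i) else x <- as.matrix(x)
    if (!all(dim(x) == c(n_s, n_i))) stop("matrix dimensions mismatch")
    storage.mode(x) <- mode
    x
  }
  gq <- fill(gq, 0L, "integer")
  if (anyNA(gq) || any(gq < 0L)) stop("gq must be non-negative integers (0 when absent)")
  ad_major <- fill(ad_major, 0L, "integer")
  ad_minor <- fill(ad_minor, 0L, "integer")
  flag <- fill(flag, FLAG_NONE, "character")
  if (!all(flag %in% c("N", "M", "E", "C"))) stop("invalid flag value")
  if (any(flag == FLAG_CORRECTED & (is.na(gt) | gt != GT_AB)))
    stop("corrected calls must be AB")
  dimnames(gt) <- dimnames(gq) <- dimnames(ad_major) <- dimnames(ad_minor) <-
    dimnames(flag) <- list(sites$site_id, samples$id)
  structure(list(sites = sites, samples = samples, gt = gt, gq = gq,
                 ad_major = ad_major, ad_minor = ad_minor, flag = flag),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", nrow(x$samples), "samples\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$samples$role)),
                                table(x$samples$role)), collapse = ", "), "\n")
  cat("  call rate:", sprintf("%.3f", mean(!is.na(x$gt))), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Indices of progeny columns
#' @param gm genotype_matrix
#' @return integer vector
#' @export
progeny_cols <- function(gm) which(gm$samples$role == "progeny")

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm genotype_matrix
#' @param sites logical/integer/character index over sites (default all)
#' @param samples logical/integer/character index over samples (default all)
#' @return genotype_matrix
#' @export
subset_genotypes <- function(gm, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(nrow(gm$sites)) else sites
  if (is.character(si)) si <- match(si, gm$sites$site_id)
  sa <- if (is.null(samples)) seq_len(nrow(gm$samples)) else samples
  if (is.character(sa)) sa <- match(sa, gm$samples$id)
  genotype_matrix(gm$sites[si, , drop = FALSE], gm$samples[sa, , drop = FALSE],
                  gm$gt[si, sa, drop = FALSE], gm$gq[si, sa, drop = FALSE],
                  gm$ad_major[si, sa, drop = FALSE], gm$ad_minor[si, sa, drop = FALSE],
                  gm$flag[si, sa, drop = FALSE])
}

#' Restrict to progeny samples
#' @param gm genotype_matrix
#' @return genotype_matrix with progeny columns only
#' @export
progeny_genotypes <- function(gm) subset_genotypes(gm, samples = progeny_cols(gm))

#' Minor allele frequency per site from genotype calls
#'
#' Frequency of the minor (B) allele among non-missing calls of the selected
#' samples.  `NaN` for sites with no calls.
#'
#' @param gm genotype_matrix
#' @param samples column index (default: progeny)
#' @return numeric vector, one value per site
#' @export
site_maf <- function(gm, samples = progeny_cols(gm)) {
  g <- gm$gt[, samples, drop = FALSE]
  rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
}

#' Encode corrected pseudo-testcross genotypes as a binary marker matrix
#'
#' Presence/absence of the minor allele in each progeny: AB -> 1, AA -> 0,
#' missing -> NA.  The input must already be error-corrected: any remaining
#' BB call is a contract violation (a pseudo-testcross site cannot produce a
#' homozygous-minor progeny).
#'
#' @param gm genotype_matrix of retained Pt markers (any non-progeny columns
#'   are ignored)
#' @return object of class `binary_markers`: list with `sites`, `progeny`
#'   (ids) and `values` (markers x progeny integer matrix 0/1/NA)
#' @export
to_binary <- function(gm) {
  pc <- progeny_cols(gm)
  if (!length(pc)) stop("no progeny samples")
  g <- gm$gt[, pc, drop = FALSE]
  if (any(g == GT_BB, na.rm = TRUE))
    stop("BB calls present: run correct_pt_genotypes() first")
  structure(list(sites = gm$sites, progeny = gm$samples$id[pc], values = g),
            class = "binary_markers")
}

#' @exportS3Method base::print
print.binary_markers <- function(x, ...) {
  cat("binary_markers:", nrow(x$sites), "markers x", length(x$progeny), "progeny;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Subset a binary marker matrix by marker ids
#' @param bm binary_markers
#' @param ids character vector of site ids (or integer index)
#' @return binary_markers
#' @export
subset_binary <- function(bm, ids) {
  i <- if (is.character(ids)) match(ids, bm$sites$site_id) else ids
  if (anyNA(i)) stop("unknown marker ids")
  structure(list(sites = bm$sites[i, , drop = FALSE], progeny = bm$progeny,
                 values = bm$values[i, , drop = FALSE]),
            class = "binary_markers")
}

#' Per-marker tallies of a binary marker matrix
#' @param bm binary_markers
#' @return data.frame with site_id, n1, n0, n_missing
#' @export
binary_counts <- function(bm) {
  v <- bm$values
  data.frame(site_id = bm$sites$site_id,
             n1 = rowSums(v == 1L, na.rm = TRUE),
             n0 = rowSums(v == 0L, na.rm = TRUE),
             n_missing = rowSums(is.na(v)),
             row.names = NULL)
}

#' Write a binary marker table as TSV
#'
#' Columns: marker id, chrom, pos, then one 0/1/NA column per progeny.
#' @param bm binary_markers
#' @param path output file
#' @return `path`, invisibly
#' @export
write_binary_table <- function(bm, path) {
  df <- cbind(data.frame(marker = bm$sites$site_id, chrom = bm$sites$chrom,
                         pos = bm$sites$pos),
              as.data.frame(bm$values))
  names(df)[-(1:3)] <- bm$progeny
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
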