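#' Read a multi-sample VCF into a genotype matrix
#'
#' Supports two allele-order dialects: `"major_minor"` (the TASSEL-GBS
#' convention, where REF/ALT are the family's major/minor alleles) and
#' `"ref_alt"` (standard VCF), in which case major/minor are determined from
#' allele frequencies across all samples and calls are re-coded so that
#' dosage counts the minor allele.  The dialect is declared, never sniffed.
#'
#' Multi-allelic sites are skipped with a warning giving the count.  Absent
#' GQ is recorded as 0 (so such calls fail every GQ >= threshold test);
#' absent AD is recorded as 0/0.  A custom `FLAG` FORMAT field (as written by
#' [write_marker_vcf()]) is read back into correction flags.
#'
#' @param path VCF file (plain or bgzipped)
#' @param allele_order `"major_minor"` (default) or `"ref_alt"`
#' @param roles optional named character vector mapping sample id -> role;
#'   samples not named are progeny.
#' @return genotype_matrix
#' @export
read_genotype_vcf <- function(path, allele_order = c("major_minor", "ref_alt"),
                              roles = NULL) {
  allele_order <- match.arg(allele_order)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi))
    warning(sum(multi), " multi-allelic or ALT-less site(s) skipped")
  keep <- which(!multi)
  if (!length(keep)) stop("no usable biallelic sites in ", path)

  gt_chr <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # dosage of ALT allele; any diploid separator accepted
  dose <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr), dimnames = dimnames(gt_chr))
  clean <- gsub("\\|", "/", gt_chr)
  dose[clean %in% c("0/0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1")] <- 2L
  bad <- !is.na(clean) & !(clean %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")) &
    !startsWith(clean, ".")
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt_chr[bad][1], "' at site ",
         fix[keep[ij[1]], "CHROM"], ":", fix[keep[ij[1]], "POS"])
  }

  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  gq <- if (is.null(gq)) matrix(0, nrow(dose), ncol(dose)) else gq[keep, , drop = FALSE]
  gq[is.na(gq)] <- 0
  ad <- vcfR::extract.gt(v, element = "AD")
  if (!is.null(ad)) ad <- ad[keep, , drop = FALSE]
  ad1 <- ad2 <- matrix(0L, nrow(dose), ncol(dose))
  if (!is.null(ad) && !all(is.na(ad))) {
    sp <- strsplit(ad, ",", fixed = TRUE)
    a1 <- suppressWarnings(as.integer(vapply(sp, function(x) x[1], "")))
    a2 <- suppressWarnings(as.integer(vapply(sp, function(x) if (length(x) > 1) x[2] else NA_character_, "")))
    ad1[] <- ifelse(is.na(a1), 0L, a1)
    ad2[] <- ifelse(is.na(a2), 0L, a2)
  }
  flg <- vcfR::extract.gt(v, element = "FLAG")
  flag <- if (is.null(flg)) matrix(FLAG_NONE, nrow(dose), ncol(dose)) else {
    f <- flg[keep, , drop = FALSE]
    f[is.na(f) | !(f %in% c("N", "M", "E", "C"))] <- FLAG_NONE
    f
  }

  major <- fix[keep, "REF"]; minor <- alt[keep]
  if (allele_order == "ref_alt") {
    # decide major/minor from sample allele frequencies; ties keep ref=major
    alt_freq <- rowSums(dose, na.rm = TRUE) / (2 * rowSums(!is.na(dose)))
    swap <- !is.na(alt_freq) & alt_freq > 0.5
    if (any(swap)) {
      tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp
      dose[swap, ] <- 2L - dose[swap, ]
      t1 <- ad1[swap, , drop = FALSE]
      ad1[swap, ] <- ad2[swap, , drop = FALSE]; ad2[swap, ] <- t1
    }
  }

  ids <- colnames(dose)
  role <- rep("progeny", length(ids))
  if (!is.null(roles)) {
    m <- match(ids, names(roles))
    role[!is.na(m)] <- roles[m[!is.na(m)]]
  }
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      major = major, minor = minor)
  genotype_matrix(sites, data.frame(id = ids, role = role),
                  dose, round(gq), ad1, ad2, flag)
}

#' Write a genotype matrix as a VCF file
#'
#' Emits VCF 4.2 with FORMAT `GT:AD:GQ:FLAG`, where FLAG records the
#' error-correction state of each call (N none, M masked, E error,
#' C corrected).  REF/ALT carry the major/minor alleles; the header documents
#' this convention.  Round-trips through [read_genotype_vcf()] with
#' `allele_order = "major_minor"`.
#'
#' @param gm genotype_matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_marker_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ptmapr",
           "##ALLELE_ORDER=major_minor (REF=major allele, ALT=minor allele within family)",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (dosage of minor allele)\">",
           "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Read depths: major,minor\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">",
           "##FORMAT=<ID=FLAG,Number=1,Type=Character,Description=\"Correction flag: N none, M masked, E error, C corrected\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", gm$samples$id), collapse = "\t"))
  writeLines(hdr, con)
  n_s <- nrow(gm$sites)
  if (n_s) {
    gtc <- matrix("./.", n_s, nrow(gm$samples))
    gtc[!is.na(gm$gt) & gm$gt == 0L] <- "0/0"
    gtc[!is.na(gm$gt) & gm$gt == 1L] <- "0/1"
    gtc[!is.na(gm$gt) & gm$gt == 2L] <- "1/1"
    cell <- matrix(paste0(gtc, ":", gm$ad_major, ",", gm$ad_minor, ":",
                          gm$gq, ":", gm$flag), n_s)
    lines <- paste(gm$sites$chrom, gm$sites$pos, gm$sites$site_id,
                   gm$sites$major, gm$sites$minor, ".", "PASS", ".",
                   "GT:AD:GQ:FLAG",
                   apply(cell, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
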