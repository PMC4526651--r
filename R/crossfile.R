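#' Export a genetic map as an R/qtl rotated ("csvsr") cross file
#'
#' Writes the rotated CSV layout: one row per phenotype (first the mandatory
#' `id` row carrying progeny ids), then one row per marker with marker id,
#' linkage group and cM position followed by one genotype code per progeny.
#' Markers appear in map order (nondecreasing cM within LG).
#'
#' Genotype codes, `BC` format: `H` = carries the minor allele (binary 1),
#' `A` = does not (binary 0), `-` = missing.  `FOURWAY` format encodes the
#' inherited parental haplotype with the female parent first; maternal
#' haplotypes are A/B and paternal haplotypes C/D, with the haplotype
#' carrying the minor allele determined by each marker's phase: 1 = AC,
#' 2 = BC, 3 = AD, 4 = BD for fully informative calls, and the
#' partially-informative codes 5 = A-, 6 = B-, 7 = -C, 8 = -D when only one
#' parent is informative at the marker (the pseudo-testcross case); `-` =
#' missing.
#'
#' @param map genetic_map (may contain LGs of both parents)
#' @param binary binary_markers holding genotypes for every map marker
#' @param path output file
#' @param format `"BC"` or `"FOURWAY"`
#' @param phenotypes optional data.frame of per-progeny phenotypes
#'   (rownames or an `id` column matching progeny ids)
#' @return `path`, invisibly
#' @export
write_crossfile <- function(map, binary, path, format = c("BC", "FOURWAY"),
                            phenotypes = NULL) {
  format <- match.arg(format)
  map <- as.data.frame(map)
  missing_m <- setdiff(map$site_id, binary$sites$site_id)
  if (length(missing_m))
    stop("map markers absent from genotypes: ",
         paste(utils::head(missing_m, 5), collapse = ", "))
  prog <- binary$progeny
  idx <- match(map$site_id, binary$sites$site_id)
  vals <- binary$values[idx, , drop = FALSE]

  if (format == "BC") {
    codes <- matrix("-", nrow(vals), ncol(vals))
    codes[!is.na(vals) & vals == 1L] <- "H"
    codes[!is.na(vals) & vals == 0L] <- "A"
  } else {
    # inherited haplotype index within the informative parent: phase if the
    # minor allele is present, the opposite haplotype otherwise
    hap <- ifelse(is.na(vals), NA_integer_,
                  ifelse(vals == 1L, map$phase[row(vals)], 1L - map$phase[row(vals)]))
    female <- map$parent[row(vals)] == "female"
    codes <- matrix("-", nrow(vals), ncol(vals))
    codes[!is.na(hap) & female & hap == 0L] <- "5"   # A-
    codes[!is.na(hap) & female & hap == 1L] <- "6"   # B-
    codes[!is.na(hap) & !female & hap == 0L] <- "7"  # -C
    codes[!is.na(hap) & !female & hap == 1L] <- "8"  # -D
  }

  ph_rows <- character(0)
  if (!is.null(phenotypes)) {
    phenotypes <- as.data.frame(phenotypes)
    pid <- if ("id" %in% names(phenotypes)) phenotypes$id else rownames(phenotypes)
    pm <- match(prog, pid)
    if (anyNA(pm)) stop("phenotypes missing for progeny: ",
                        paste(utils::head(prog[is.na(pm)], 5), collapse = ", "))
    pcols <- setdiff(names(phenotypes), "id")
    ph_rows <- vapply(pcols, function(p) {
      paste(c(p, "", "", as.character(phenotypes[[p]][pm])), collapse = ",")
    }, "")
  }
  lines <- c(paste(c("id", "", "", prog), collapse = ","),
             ph_rows,
             vapply(seq_len(nrow(map)), function(i) {
               paste(c(map$site_id[i], map$lg[i], format(round(map$cM[i], 3)),
                       codes[i, ]), collapse = ",")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a rotated cross file written by [write_crossfile()]
#'
#' @param path file path
#' @return list with `markers` (data.frame marker/lg/cM), `geno` (character
#'   matrix markers x progeny), `progeny`, `phenotypes` (data.frame or NULL)
#' @export
read_crossfile <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character")
  if (raw[1, 1] != "id") stop("not a csvsr cross file: first row must be 'id'")
  prog <- as.character(raw[1, -(1:3)])
  body <- raw[-1, , drop = FALSE]
  is_ph <- body[, 2] == "" & body[, 3] == ""
  ph <- NULL
  if (any(is_ph)) {
    ph <- as.data.frame(t(body[is_ph, -(1:3), drop = FALSE]))
    names(ph) <- body[is_ph, 1]
    ph <- cbind(id = prog, ph)
    rownames(ph) <- NULL
  }
  mk <- body[!is_ph, , drop = FALSE]
  geno <- as.matrix(mk[, -(1:3), drop = FALSE])
  dimnames(geno) <- list(mk[, 1], prog)
  list(markers = data.frame(marker = mk[, 1], lg = mk[, 2],
                            cM = as.numeric(mk[, 3]), row.names = NULL),
       geno = geno, progeny = prog, phenotypes = ph)
}
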