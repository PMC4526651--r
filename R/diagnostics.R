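#' Minor allele and minor tag frequency profile
#'
#' Per site: MAF from genotype calls and MTF — the minor-allele read depth
#' divided by the total read depth, pooled across progeny.  A normal Pt site
#' has expected MTF 0.25; a tag collapsing two duplicated regions halves the
#' minor-read fraction to 0.125 (1:7 segregation), which shows as a second
#' mode in the MTF distribution while the MAF distribution stays unimodal.
#' Kernel density estimates (Silverman bandwidth) and their local maxima are
#' returned per status class.
#'
#' @param gm genotype_matrix carrying AD fields
#' @param final_ids site ids in the final map
#' @param removed_ids site ids removed during curation
#' @return list with `stats` (site_id, maf, mtf, status), `density` (per
#'   status: data.frames x/y for MAF and MTF), `modes` (per status: MTF mode
#'   locations)
#' @export
maf_mtf_profile <- function(gm, final_ids, removed_ids = character(0)) {
  prog <- progeny_cols(gm)
  dmin <- rowSums(gm$ad_minor[, prog, drop = FALSE])
  dtot <- dmin + rowSums(gm$ad_major[, prog, drop = FALSE])
  if (all(dtot == 0)) warning("no read depth information; MTF missing")
  mtf <- ifelse(dtot > 0, dmin / dtot, NA_real_)
  maf <- site_maf(gm, prog)
  status <- rep(NA_character_, nrow(gm$sites))
  status[gm$sites$site_id %in% final_ids] <- "final_map"
  status[gm$sites$site_id %in% removed_ids] <- "removed"
  stats_df <- data.frame(site_id = gm$sites$site_id, maf = maf, mtf = mtf,
                         status = status, row.names = NULL)
  dens_modes <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 5) return(list(density = NULL, modes = numeric(0)))
    d <- stats::density(v, bw = "nrd0")
    i <- which(diff(sign(diff(d$y))) == -2) + 1
    list(density = data.frame(x = d$x, y = d$y), modes = d$x[i])
  }
  out_density <- list(); out_modes <- list()
  for (s in c("final_map", "removed")) {
    sel <- !is.na(status) & status == s
    dm <- dens_modes(mtf[sel])
    out_density[[s]] <- list(mtf = dm$density,
                             maf = dens_modes(maf[sel])$density)
    out_modes[[s]] <- dm$modes
  }
  list(stats = stats_df, density = out_density, modes = out_modes)
}

#' Sliding-window genome statistics
#'
#' Tiles each chromosome with half-open windows `[start, start + size)`
#' advanced by `slide`: per window the marker count, mean MAF and
#' recombination frequency (obligate crossovers per progeny per Mb, each
#' crossover located at the midpoint of its bracketing marker pair) are
#' reported.  Contiguous runs of windows with mean MAF below `maf_lo` or
#' above `maf_hi` are merged into segregation-distortion regions.
#'
#' @param gm genotype_matrix (physical positions)
#' @param map genetic_map (phased, ordered; used for crossover locations)
#' @param bm binary_markers backing the map
#' @param window window size in bp (default 1 Mb)
#' @param slide step in bp (default 100 kb)
#' @param maf_lo,maf_hi distortion thresholds on window mean MAF
#' @return list with `windows` (chrom/start/end/n_snps/mean_maf/recomb_freq)
#'   and `distortion` (chrom/start/end extents)
#' @export
windowed_genome_stats <- function(gm, map = NULL, bm = NULL,
                                  window = 1e6, slide = 1e5,
                                  maf_lo = 0.20, maf_hi = 0.30) {
  maf <- site_maf(gm)
  res <- list()
  xo_events <- NULL
  if (!is.null(map) && !is.null(bm)) {
    n_prog <- length(bm$progeny)
    ev <- list()
    for (e in map) {
      x <- lg_matrix(e, bm)
      pos <- gm$sites$pos[match(e$markers, gm$sites$site_id)]
      ch <- gm$sites$chrom[match(e$markers, gm$sites$site_id)]
      for (j in seq_len(ncol(x))) {
        v <- x[, j]; obs <- which(!is.na(v))
        if (length(obs) < 2) next
        sw <- obs[which(diff(v[obs]) != 0L)]
        nx <- obs[which(diff(v[obs]) != 0L) + 1L]
        if (!length(sw)) next
        ev[[length(ev) + 1L]] <- data.frame(chrom = ch[sw],
                                            pos = (pos[sw] + pos[nx]) / 2)
      }
    }
    if (length(ev)) xo_events <- do.call(rbind, ev)
  } else n_prog <- length(progeny_cols(gm))
  for (ch in unique(gm$sites$chrom)) {
    sel <- gm$sites$chrom == ch
    pos <- gm$sites$pos[sel]
    mafs <- maf[sel]
    starts <- seq(1, max(pos), by = slide)
    ends <- starts + window
    n_snps <- mean_maf <- rec <- numeric(length(starts))
    for (i in seq_along(starts)) {
      inw <- pos >= starts[i] & pos < ends[i]
      n_snps[i] <- sum(inw)
      mean_maf[i] <- if (any(inw)) mean(mafs[inw], na.rm = TRUE) else NA_real_
      if (!is.null(xo_events)) {
        nx <- sum(xo_events$chrom == ch & xo_events$pos >= starts[i] &
                    xo_events$pos < ends[i])
        rec[i] <- nx / n_prog / (window / 1e6)
      }
    }
    res[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            n_snps = n_snps, mean_maf = mean_maf,
                            recomb_freq = rec)
  }
  win <- do.call(rbind, res)
  rownames(win) <- NULL
  distorted <- !is.na(win$mean_maf) &
    (win$mean_maf < maf_lo | win$mean_maf > maf_hi) & win$n_snps > 0
  regions <- list()
  for (ch in unique(win$chrom)) {
    w <- win[win$chrom == ch & distorted, , drop = FALSE]
    if (!nrow(w)) next
    w <- w[order(w$start), ]
    s <- w$start[1]; e <- w$end[1]
    for (i in seq_len(nrow(w))[-1]) {
      if (w$start[i] <= e) e <- max(e, w$end[i])
      else { regions[[length(regions) + 1L]] <- data.frame(chrom = ch, start = s, end = e); s <- w$start[i]; e <- w$end[i] }
    }
    regions[[length(regions) + 1L]] <- data.frame(chrom = ch, start = s, end = e)
  }
  distortion <- if (length(regions)) do.call(rbind, regions)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  list(windows = win, distortion = distortion)
}
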