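#' Grid sweep over static cut heights and minimum cluster sizes
#'
#' The topological-overlap tree of the full Pt marker set is built once and
#' cut at every (height, minimum size) combination.  The selected pair is
#' the one producing at least `2 * n_chrom` linkage groups — two parental
#' LGs per chromosome — while maximising the fraction of markers assigned;
#' ties prefer the larger minimum size (fewer spurious LGs) and then the
#' lower height.  When no grid point reaches the LG target the best-effort
#' point (maximum assigned fraction) is reported with `selected_ok = FALSE`.
#'
#' @param bm binary_markers of the Pt set
#' @param heights cut heights to try (defaults to the published grid)
#' @param min_sizes minimum cluster sizes to try (defaults to the published
#'   grid)
#' @param n_chrom expected chromosome count (default 19)
#' @param min_pairs forwarded to [binary_correlation_matrix()]
#' @return list of class `lg_sweep`: `grid` (data.frame height, min_size,
#'   n_lgs, fraction_assigned), `selected` (row of `grid`), `selected_ok`,
#'   `labels` (cluster labels at the selected point), `correlation`, `tree`
#' @export
sweep_and_select <- function(bm,
                             heights = c(0.95, 0.9375, 0.925, 0.9125, 0.9,
                                         0.8875, 0.875, 0.8625, 0.85),
                             min_sizes = c(50, 100, 150, 200, 250, 300),
                             n_chrom = 19, min_pairs = 20) {
  if (nrow(bm$sites) < 2) stop("need at least two markers")
  if (!length(heights) || !length(min_sizes)) stop("empty parameter grid")
  cm <- binary_correlation_matrix(bm, min_pairs = min_pairs)
  adj <- cm$r^2
  adj[is.na(adj)] <- 0
  d <- tom_distance(adj)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  grid <- expand.grid(height = heights, min_size = min_sizes,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    lab <- suppressWarnings(
      cluster_static_cut(d, grid$height[i], grid$min_size[i], tree = tree))
    c(n_lgs = length(setdiff(unique(lab), 0L)),
      fraction_assigned = mean(lab > 0L))
  })
  grid$n_lgs <- vapply(res, `[[`, 0, "n_lgs")
  grid$fraction_assigned <- vapply(res, `[[`, 0, "fraction_assigned")
  ok <- grid$n_lgs >= 2 * n_chrom
  pool <- if (any(ok)) which(ok) else seq_len(nrow(grid))
  sel <- pool[order(-grid$fraction_assigned[pool], -grid$min_size[pool],
                    grid$height[pool])][1]
  labels <- suppressWarnings(
    cluster_static_cut(d, grid$height[sel], grid$min_size[sel], tree = tree))
  structure(list(grid = grid, selected = grid[sel, , drop = FALSE],
                 selected_ok = any(ok), labels = labels,
                 correlation = cm, tree = tree),
            class = "lg_sweep")
}

#' @exportS3Method base::print
print.lg_sweep <- function(x, ...) {
  cat("lg_sweep:", nrow(x$grid), "grid points; selected height",
      x$selected$height, "min size", x$selected$min_size, "->",
      x$selected$n_lgs, "LGs,",
      sprintf("%.1f%% assigned", 100 * x$selected$fraction_assigned),
      if (!x$selected_ok) "(LG target not reached)" else "", "\n")
  invisible(x)
}

#' Reference-free (de novo) linkage-group formation
#'
#' Takes the clustering selected by [sweep_and_select()], removes
#' mis-assigned markers with the squared-correlation diff filter (each
#' marker tested against every LG, with its own LG as the assigned group;
#' disagreeing and unresolved markers are dropped), phases every surviving
#' LG, and flags LGs with an atypical linkage pattern — phasing failure or
#' mean within-LG r^2 below `atypical_r2_floor` — for manual exclusion.
#'
#' @param bm binary_markers of the Pt set
#' @param sweep lg_sweep from [sweep_and_select()]
#' @param diff ratio threshold for the mis-assignment filter
#' @param phase_cut_height,min_phase_size phasing parameters (defaults 0.9
#'   and 10)
#' @param atypical_r2_floor minimum mean within-LG r^2
#' @return list with `lgs` (list of linkage_group), `verdicts`, `atypical`
#'   (character vector of flagged LG ids)
#' @export
build_denovo_lgs <- function(bm, sweep, diff = 2, phase_cut_height = 0.9,
                             min_phase_size = 10, atypical_r2_floor = 0.02) {
  lab <- sweep$labels
  assigned <- lab[lab > 0L]
  if (!length(assigned)) stop("sweep assigned no markers")
  groups <- split(names(assigned), assigned)
  vd <- diff_filter(stats::setNames(as.character(assigned), names(assigned)),
                    groups, sweep$correlation, diff = diff, mode = "squared")
  keep <- vd$marker[vd$verdict == "agree"]
  lgs <- list(); atypical <- character(0)
  for (g in names(groups)) {
    mids <- intersect(groups[[g]], keep)
    if (length(mids) < 2 * min_phase_size) {
      atypical <- c(atypical, paste0("LG", g))
      next
    }
    r_block <- sweep$correlation$r[mids, mids]
    mean_r2 <- mean(r_block[upper.tri(r_block)]^2, na.rm = TRUE)
    ph <- tryCatch(
      phase_linkage_group(mids, bm, cut_height = phase_cut_height,
                          min_phase_size = min_phase_size),
      error = function(e) structure(data.frame(marker = mids,
                                               phase = NA_integer_),
                                    phased = FALSE))
    lg <- linkage_group(lg_id = paste0("LG", g),
                        markers = data.frame(marker = ph$marker,
                                             phase = ph$phase),
                        provenance = "denovo")
    if (!isTRUE(attr(ph, "phased")) || mean_r2 < atypical_r2_floor)
      atypical <- c(atypical, lg$lg_id)
    lgs[[length(lgs) + 1L]] <- lg
  }
  list(lgs = lgs, verdicts = vd, atypical = atypical)
}
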