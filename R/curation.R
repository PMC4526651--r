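#' Curation parameters
#'
#' Thresholds of the five-step map curation: markers with >= 50% missing and
#' individuals with > 50% missing or more than twice the family-mean
#' crossover count are removed; order diagnostics flag adjacent pairs with
#' rf > 0.4 or LOD < 1; genotyping error is estimated on a log-spaced grid;
#' the drop-one scan uses a 9-marker window, removes markers that shorten
#' the map by more than 2 cM with a LOD difference above the chosen
#' threshold (by default the 95th percentile of the scan's LOD-difference
#' distribution, i.e. the upper tail of the histogram); gaps over 2 cM are
#' flagged; final rippling uses a 7-marker window.
#'
#' @param marker_missing_max maximum marker missing fraction (removal at >=)
#' @param individual_missing_max maximum individual missing fraction
#'   (removal at >)
#' @param crossover_multiple crossover-excess multiplier (removal at
#'   strictly more than multiple x family mean)
#' @param dropone_window drop-one scan window (odd)
#' @param gap_max_cM gap flagging threshold
#' @param ripple_window ripple window (odd)
#' @param error_prob_grid candidate genotyping error rates
#' @param lod_diff_quantile quantile defining the default drop-one LOD
#'   threshold
#' @param lod_diff_threshold explicit LOD threshold (overrides the quantile
#'   rule when set)
#' @param rf_flag,lod_flag adjacent-pair diagnostic thresholds
#' @return list of class `curation_params`
#' @export
curation_params <- function(marker_missing_max = 0.5,
                            individual_missing_max = 0.5,
                            crossover_multiple = 2,
                            dropone_window = 9, gap_max_cM = 2,
                            ripple_window = 7,
                            error_prob_grid = 10^seq(log10(1e-4), log10(0.2),
                                                     length.out = 13),
                            lod_diff_quantile = 0.95,
                            lod_diff_threshold = NULL,
                            rf_flag = 0.4, lod_flag = 1) {
  stopifnot(dropone_window %% 2 == 1, ripple_window %% 2 == 1,
            all(error_prob_grid > 0), all(error_prob_grid < 0.5))
  structure(list(marker_missing_max = marker_missing_max,
                 individual_missing_max = individual_missing_max,
                 crossover_multiple = crossover_multiple,
                 dropone_window = dropone_window, gap_max_cM = gap_max_cM,
                 ripple_window = ripple_window,
                 error_prob_grid = error_prob_grid,
                 lod_diff_quantile = lod_diff_quantile,
                 lod_diff_threshold = lod_diff_threshold,
                 rf_flag = rf_flag, lod_flag = lod_flag),
            class = "curation_params")
}

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log(exp(a - m) + exp(b - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

.clamp_r <- function(r) pmin(pmax(r, 1e-6), 0.5 - 1e-6)

# emission log-probabilities for phase-encoded data; missing emits 1
.emis <- function(xrow, eps) {
  e0 <- ifelse(is.na(xrow), 0, ifelse(xrow == 0L, log(1 - eps), log(eps)))
  e1 <- ifelse(is.na(xrow), 0, ifelse(xrow == 1L, log(1 - eps), log(eps)))
  list(e0 = e0, e1 = e1)
}

#' Forward log-likelihood of a linkage group under the phase HMM
#'
#' Two hidden states (parental phase 0/1) per progeny along the ordered
#' markers; the transition probability between adjacent markers is the
#' inter-marker recombination fraction, the observed call equals the hidden
#' phase with probability `1 - eps`, and missing observations are
#' uninformative.
#'
#' @param x phase-encoded matrix (ordered markers x progeny, 0/1/NA)
#' @param r adjacent recombination fractions (length `nrow(x) - 1`)
#' @param eps genotyping error probability
#' @return total log-likelihood summed over progeny; attribute
#'   `"per_progeny"` carries the per-progeny values
#' @export
hmm_loglik <- function(x, r, eps) {
  m <- nrow(x)
  stopifnot(length(r) == m - 1, eps > 0, eps < 0.5)
  r <- .clamp_r(r)
  em <- .emis(x[1, ], eps)
  a0 <- log(0.5) + em$e0; a1 <- log(0.5) + em$e1
  for (j in seq_len(m - 1)) {
    st <- log(1 - r[j]); sw <- log(r[j])
    em <- .emis(x[j + 1, ], eps)
    b0 <- .logsumexp2(a0 + st, a1 + sw) + em$e0
    b1 <- .logsumexp2(a0 + sw, a1 + st) + em$e1
    a0 <- b0; a1 <- b1
  }
  per <- .logsumexp2(a0, a1)
  structure(sum(per), per_progeny = per)
}

# forward-backward posterior switch probabilities per interval, summed over
# progeny; returns updated r estimates
.hmm_rf_update <- function(x, r, eps) {
  m <- nrow(x); n <- ncol(x)
  r <- .clamp_r(r)
  E0 <- E1 <- matrix(0, m, n)
  for (j in seq_len(m)) {
    em <- .emis(x[j, ], eps)
    E0[j, ] <- em$e0; E1[j, ] <- em$e1
  }
  A0 <- A1 <- B0 <- B1 <- matrix(0, m, n)
  A0[1, ] <- log(0.5) + E0[1, ]; A1[1, ] <- log(0.5) + E1[1, ]
  for (j in seq_len(m - 1)) {
    st <- log(1 - r[j]); sw <- log(r[j])
    A0[j + 1, ] <- .logsumexp2(A0[j, ] + st, A1[j, ] + sw) + E0[j + 1, ]
    A1[j + 1, ] <- .logsumexp2(A0[j, ] + sw, A1[j, ] + st) + E1[j + 1, ]
  }
  B0[m, ] <- 0; B1[m, ] <- 0
  for (j in rev(seq_len(m - 1))) {
    st <- log(1 - r[j]); sw <- log(r[j])
    B0[j, ] <- .logsumexp2(st + E0[j + 1, ] + B0[j + 1, ],
                           sw + E1[j + 1, ] + B1[j + 1, ])
    B1[j, ] <- .logsumexp2(sw + E0[j + 1, ] + B0[j + 1, ],
                           st + E1[j + 1, ] + B1[j + 1, ])
  }
  ll <- .logsumexp2(A0[m, ], A1[m, ])
  r_new <- numeric(m - 1)
  for (j in seq_len(m - 1)) {
    st <- log(1 - r[j]); sw <- log(r[j])
    sw01 <- A0[j, ] + sw + E1[j + 1, ] + B1[j + 1, ] - ll
    sw10 <- A1[j, ] + sw + E0[j + 1, ] + B0[j + 1, ] - ll
    r_new[j] <- sum(exp(.logsumexp2(sw01, sw10))) / n
  }
  .clamp_r(r_new)
}

#' Estimate the genotyping error rate of an ordered linkage group
#'
#' A profile likelihood over a grid of candidate error probabilities: at
#' each grid point the inter-marker recombination fractions are re-estimated
#' with a bounded number of EM (forward-backward) updates and the resulting
#' log-likelihood recorded; the maximiser is returned together with the
#' fractions re-estimated at it.  (Evaluating the grid at the raw, error
#' inflated rf estimates would bias the error rate low, since inflated
#' transition probabilities absorb isolated flips as crossovers.)
#'
#' @param x phase-encoded ordered matrix (>= 3 markers)
#' @param r_init initial adjacent rf estimates (defaults to raw discordance)
#' @param params curation_params (supplies the grid)
#' @param em_iter EM iterations for the rf re-estimation
#' @return list with `eps_hat`, `loglik` (data.frame eps/loglik), `rf`
#'   (re-estimated adjacent fractions), `cM` (positions from the
#'   re-estimated fractions)
#' @export
estimate_error_rate <- function(x, r_init = NULL, params = curation_params(),
                                em_iter = 3) {
  m <- nrow(x)
  if (m < 3) stop("need at least 3 markers")
  if (is.null(r_init)) {
    st <- pairwise_rf(x, min_pairs = 1)
    r_init <- st$rf[cbind(1:(m - 1), 2:m)]
    r_init[is.na(r_init)] <- 0.25
  }
  r_init <- .clamp_r(r_init)
  grid <- params$error_prob_grid
  ll <- vapply(grid, function(e) {
    r <- r_init
    for (it in seq_len(em_iter)) r <- .hmm_rf_update(x, r, e)
    as.numeric(hmm_loglik(x, r, e))
  }, 0)
  eps_hat <- grid[which.max(ll)]
  r <- r_init
  for (it in seq_len(em_iter)) r <- .hmm_rf_update(x, r, eps_hat)
  cM <- c(0, cumsum(suppressWarnings(kosambi(r))))
  names(cM) <- rownames(x)
  list(eps_hat = eps_hat, loglik = data.frame(eps = grid, loglik = ll),
       rf = r, cM = cM)
}

#' Obligate crossover counts per individual
#'
#' Number of phase switches between consecutive non-missing calls along the
#' ordered markers, summed over the supplied matrices (one per LG).
#'
#' @param xs list of phase-encoded ordered matrices
#' @return integer vector per progeny
#' @export
obligate_crossovers <- function(xs) {
  if (is.matrix(xs)) xs <- list(xs)
  n <- ncol(xs[[1]])
  total <- integer(n)
  for (x in xs) {
    total <- total + vapply(seq_len(n), function(j) {
      v <- x[, j]; v <- v[!is.na(v)]
      if (length(v) < 2) 0L else sum(diff(v) != 0L)
    }, 0L)
  }
  total
}

#' Curation step 1: missing-data and crossover-excess filters
#'
#' Markers with at least `marker_missing_max` missing calls are removed
#' first; then individuals with more than `individual_missing_max` missing
#' genotypes across the map, or with strictly more than
#' `crossover_multiple` times the family-mean obligate crossover count, are
#' removed.
#'
#' @param map genetic_map
#' @param bm binary_markers backing it
#' @param params curation_params
#' @return list with `map` (markers filtered, positions recomputed), `bm`
#'   (individuals removed), `removed_markers`, `removed_individuals`
#' @export
filter_missing_and_crossovers <- function(map, bm, params = curation_params()) {
  removed_markers <- character(0)
  for (i in seq_along(map)) {
    e <- map[[i]]
    x <- lg_matrix(e, bm)
    miss <- rowMeans(is.na(x))
    drop <- e$markers[miss >= params$marker_missing_max]
    removed_markers <- c(removed_markers, drop)
    if (length(drop)) map[[i]] <- .refresh_entry(e, setdiff(e$markers, drop), bm)
  }
  xs <- lapply(map, lg_matrix, bm = bm)
  miss_ind <- rowMeans(do.call(rbind, lapply(xs, function(x) colMeans(is.na(x)))))
  xo <- obligate_crossovers(xs)
  bad <- miss_ind > params$individual_missing_max |
    xo > params$crossover_multiple * mean(xo)
  if (all(bad)) stop("all individuals removed")
  removed_individuals <- bm$progeny[bad]
  if (any(bad)) {
    bm$values <- bm$values[, !bad, drop = FALSE]
    bm$progeny <- bm$progeny[!bad]
    for (i in seq_along(map))
      map[[i]] <- .refresh_entry(map[[i]], map[[i]]$markers, bm)
  }
  list(map = map, bm = bm, removed_markers = removed_markers,
       removed_individuals = removed_individuals)
}

# phase-encoded matrix of a map entry, in map order
lg_matrix <- function(entry, bm) {
  x <- subset_binary(bm, entry$markers)$values
  flip <- entry$phase == 1L
  x[flip, ] <- 1L - x[flip, ]
  x
}

# recompute an entry for a (possibly reduced) marker set, keeping order
.refresh_entry <- function(entry, markers, bm) {
  keep <- entry$markers[entry$markers %in% markers]
  entry$markers <- keep
  entry$phase <- entry$phase[keep]
  x <- lg_matrix(entry, bm)
  mp <- map_positions(keep, x)
  entry$cM <- mp$cM; entry$rf <- mp$rf
  entry
}

#' Curation step 4: drop-one-marker scan
#'
#' For each interior marker, within a sliding window (default 9 markers) the
#' HMM log-likelihood and window map length are compared with and without
#' the marker: the without-marker likelihood uses the remaining markers'
#' data with the direct rf between the new neighbours re-estimated, while
#' the with-marker reference treats the focal marker's column as missing so
#' both terms score the same observations.  Markers whose removal shortens
#' the window by more than `gap_max_cM` (2 cM) and whose LOD difference
#' exceeds the threshold — by default the `lod_diff_quantile` upper tail of
#' the scan's own LOD-difference distribution — are removed.  Terminal
#' markers are never removed (dropping an end marker always trims the map).
#'
#' @param entry one genetic_map entry (list with markers/phase/cM/rf)
#' @param bm binary_markers
#' @param eps_hat genotyping error rate for the HMM
#' @param params curation_params
#' @param lod_threshold optional fixed threshold (otherwise quantile rule)
#' @return list with `scan` (data.frame marker/delta_cM/lod_diff),
#'   `removed`, `entry` (refreshed after removals)
#' @export
drop_one_marker_scan <- function(entry, bm, eps_hat,
                                 params = curation_params(),
                                 lod_threshold = NULL) {
  scan <- dropone_scan_values(entry, bm, eps_hat, params)
  thr <- lod_threshold %||% params$lod_diff_threshold %||%
    stats::quantile(scan$lod_diff, params$lod_diff_quantile, na.rm = TRUE,
                    names = FALSE)
  removed <- scan$marker[!is.na(scan$delta_cM) &
                           scan$delta_cM > params$gap_max_cM &
                           !is.na(scan$lod_diff) & scan$lod_diff > thr]
  if (length(removed))
    entry <- .refresh_entry(entry, setdiff(entry$markers, removed), bm)
  list(scan = scan, removed = removed, entry = entry, lod_threshold = thr)
}

#' Curation step 5: gap flags, ripple, orientation, final distances
#'
#' Flags markers creating gaps larger than `gap_max_cM` (report only),
#' ripples the order with an exhaustive sliding-window search (default 7
#' markers) minimising total obligate crossovers, inverts the LG when its
#' genetic order anticorrelates with the physical positions, and recomputes
#' Kosambi distances (error-corrected via the HMM when `eps_hat` is given).
#'
#' @param entry genetic_map entry
#' @param bm binary_markers
#' @param sites site metadata (for physical orientation); may be NULL
#' @param eps_hat error rate for the final distance re-estimation (NULL for
#'   raw distances)
#' @param params curation_params
#' @return list with `entry` (finalised), `gap_markers` (flagged ids),
#'   `inverted` (logical)
#' @export
ripple_and_finalize <- function(entry, bm, sites = NULL, eps_hat = NULL,
                                params = curation_params()) {
  x <- lg_matrix(entry, bm)
  st <- pairwise_rf(x, min_pairs = 1)
  ord <- .polish_order(seq_along(entry$markers), st$R,
                       window = params$ripple_window)
  entry$markers <- entry$markers[ord]
  entry$phase <- entry$phase[ord]
  x <- x[ord, , drop = FALSE]
  mp <- map_positions(entry$markers, x)
  entry$cM <- mp$cM; entry$rf <- mp$rf
  inverted <- FALSE
  if (!is.null(sites)) {
    pos <- sites$pos[match(entry$markers, sites$site_id)]
    ch <- sites$chrom[match(entry$markers, sites$site_id)]
    main <- names(sort(table(ch), decreasing = TRUE))[1]
    use <- !is.na(pos) & ch == main
    if (sum(use) >= 3) {
      rho <- suppressWarnings(stats::cor(entry$cM[use], pos[use],
                                         method = "spearman"))
      if (!is.na(rho) && rho < 0) {
        inverted <- TRUE
        entry$markers <- rev(entry$markers)
        entry$phase <- rev(entry$phase)
        x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
        mp <- map_positions(entry$markers, x)
        entry$cM <- mp$cM; entry$rf <- mp$rf
      }
    }
  }
  if (!is.null(eps_hat) && length(entry$markers) >= 3) {
    r <- entry$rf
    for (it in 1:3) r <- .hmm_rf_update(x, r, eps_hat)
    entry$rf <- r
    entry$cM <- stats::setNames(c(0, cumsum(suppressWarnings(kosambi(r)))),
                                entry$markers)
  }
  gaps <- which(diff(entry$cM) > params$gap_max_cM)
  list(entry = entry, gap_markers = entry$markers[gaps + 1], inverted = inverted)
}

#' Five-step map curation
#'
#' Runs the full curation procedure on an ordered genetic map:
#' (1) missing-data and crossover-excess filters; (2) order diagnostics —
#' adjacent pairs with rf above `rf_flag` or LOD below `lod_flag` trigger a
#' windowed re-polish of the LG; (3) per-LG genotyping-error estimation and
#' error-corrected distance re-estimation; (4) drop-one-marker scan with the
#' histogram-derived LOD threshold; (5) gap flagging, rippling, physical
#' orientation and final Kosambi distances.  Distances are recomputed after
#' every destructive step.
#'
#' @param map genetic_map from [build_genetic_map()]
#' @param bm binary_markers
#' @param params curation_params
#' @param sites optional site metadata for orientation
#' @return list with `map` (curated genetic_map), `bm` (individuals
#'   filtered), `report` (per-stage marker counts and lengths, per-LG
#'   eps_hat, removals, drop-one LOD values, gap flags)
#' @export
curate_map <- function(map, bm, params = curation_params(), sites = NULL) {
  stage <- function(map) c(markers = sum(lengths(lapply(map, `[[`, "markers"))),
                           cM = sum(map_lengths(map)))
  report <- list(initial = stage(map))

  s1 <- filter_missing_and_crossovers(map, bm, params)
  map <- s1$map; bm <- s1$bm
  report$step1 <- stage(map)

  # step 2: diagnostics + targeted re-polish
  for (i in seq_along(map)) {
    e <- map[[i]]
    x <- lg_matrix(e, bm)
    st <- pairwise_rf(x, min_pairs = 1)
    adj_rf <- e$rf
    adj_lod <- st$lod[cbind(seq_along(adj_rf), seq_along(adj_rf) + 1)]
    if (any(adj_rf > params$rf_flag | adj_lod < params$lod_flag, na.rm = TRUE)) {
      ord <- .polish_order(seq_along(e$markers), st$R, window = 5)
      e$markers <- e$markers[ord]
      e$phase <- e$phase[ord]
      x2 <- lg_matrix(e, bm)
      mp <- map_positions(e$markers, x2)
      e$cM <- mp$cM; e$rf <- mp$rf
      map[[i]] <- e
    }
  }
  report$step2 <- stage(map)

  # step 3: error-rate estimation and corrected distances
  eps <- numeric(length(map))
  for (i in seq_along(map)) {
    e <- map[[i]]
    if (length(e$markers) < 3) { eps[i] <- NA_real_; next }
    x <- lg_matrix(e, bm)
    est <- estimate_error_rate(x, r_init = e$rf, params = params)
    eps[i] <- est$eps_hat
    map[[i]]$rf <- est$rf
    map[[i]]$cM <- est$cM
  }
  report$eps_hat <- stats::setNames(eps, vapply(map, `[[`, "", "lg_id"))
  report$step3 <- stage(map)

  # step 4: drop-one scan with a map-level threshold
  scans <- lapply(seq_along(map), function(i) {
    if (length(map[[i]]$markers) < 5) return(NULL)
    dropone_scan_values(map[[i]], bm, eps[i], params)
  })
  all_lod <- unlist(lapply(scans, function(s) s$lod_diff))
  thr <- params$lod_diff_threshold %||%
    stats::quantile(all_lod, params$lod_diff_quantile, na.rm = TRUE,
                    names = FALSE)
  dropped <- character(0)
  for (i in seq_along(map)) {
    s <- scans[[i]]
    if (is.null(s)) next
    rm_ <- s$marker[!is.na(s$delta_cM) & s$delta_cM > params$gap_max_cM &
                      !is.na(s$lod_diff) & s$lod_diff > thr]
    if (length(rm_)) {
      dropped <- c(dropped, rm_)
      map[[i]] <- .refresh_entry(map[[i]], setdiff(map[[i]]$markers, rm_), bm)
      x <- lg_matrix(map[[i]], bm)
      r <- map[[i]]$rf
      if (length(map[[i]]$markers) >= 3 && !is.na(eps[i])) {
        for (it in 1:2) r <- .hmm_rf_update(x, r, eps[i])
        map[[i]]$rf <- r
        map[[i]]$cM <- stats::setNames(
          c(0, cumsum(suppressWarnings(kosambi(r)))), map[[i]]$markers)
      }
    }
  }
  report$dropone <- list(lod_values = all_lod, threshold = thr,
                         removed = dropped)
  report$step4 <- stage(map)

  # step 5: ripple, orient, finalize
  gaps <- list()
  for (i in seq_along(map)) {
    fin <- ripple_and_finalize(map[[i]], bm, sites = sites,
                               eps_hat = if (is.na(eps[i])) NULL else eps[i],
                               params = params)
    map[[i]] <- fin$entry
    gaps[[map[[i]]$lg_id]] <- fin$gap_markers
  }
  report$gap_markers <- gaps
  report$final <- stage(map)
  report$removed_markers <- c(s1$removed_markers, dropped)
  report$removed_individuals <- s1$removed_individuals
  list(map = map, bm = bm, report = report)
}

# raw drop-one statistics for one LG (no removal)
dropone_scan_values <- function(entry, bm, eps_hat, params) {
  x <- lg_matrix(entry, bm)
  m <- nrow(x)
  st <- pairwise_rf(x, min_pairs = 1)
  raw_rf <- function(i, j) {
    r <- st$rf[i, j]
    if (is.na(r)) 0.25 else .clamp_r(r)
  }
  half <- (params$dropone_window - 1) / 2
  delta <- lodd <- rep(NA_real_, m)
  for (j in 2:(m - 1)) {
    w <- max(1, j - half):min(m, j + half)
    jj <- match(j, w)
    r_w <- vapply(seq_len(length(w) - 1), function(k) raw_rf(w[k], w[k + 1]), 0)
    x_mask <- x[w, , drop = FALSE]; x_mask[jj, ] <- NA_integer_
    ll_with <- as.numeric(hmm_loglik(x_mask, r_w, eps_hat))
    wo <- w[-jj]
    r_wo <- vapply(seq_len(length(wo) - 1), function(k) raw_rf(wo[k], wo[k + 1]), 0)
    ll_wo <- as.numeric(hmm_loglik(x[wo, , drop = FALSE], r_wo, eps_hat))
    lodd[j] <- (ll_wo - ll_with) / log(10)
    delta[j] <- suppressWarnings(kosambi(raw_rf(j - 1, j)) +
                                   kosambi(raw_rf(j, j + 1)) -
                                   kosambi(raw_rf(j - 1, j + 1)))
  }
  data.frame(marker = entry$markers, delta_cM = delta, lod_diff = lodd)
}
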