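#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a recombination fraction r to map distance
#' `d = 25 ln((1 + 2r) / (1 - 2r))` cM; `kosambi_inv()` maps a distance back
#' to \eqn{r = \tanh(d/50)/2}.  Fractions at or above 0.5 are capped at
#' `max_cM` with a warning; negative fractions are an error.
#'
#' @param r recombination fraction(s) in [0, 0.5)
#' @param max_cM distance assigned to unlinked pairs (default 50)
#' @return distance in cM
#' @export
kosambi <- function(r, max_cM = 50) {
  if (any(r < 0, na.rm = TRUE)) stop("negative recombination fraction")
  out <- 25 * log((1 + 2 * r) / (1 - 2 * r))
  if (any(r >= 0.5, na.rm = TRUE)) {
    warning("recombination fraction >= 0.5 capped at ", max_cM, " cM")
    out[r >= 0.5] <- max_cM
  }
  out
}

#' @rdname kosambi
#' @param d map distance(s) in cM
#' @export
kosambi_inv <- function(d) tanh(d / 50) / 2

#' Phase-encode binary genotypes of one linkage group
#'
#' Rows of phase-1 markers are complemented so that every row records
#' inheritance of the same parental haplotype (1 = phase-0 haplotype).  This
#' is what makes the backcross/DH two-point machinery valid for
#' pseudo-testcross markers.
#'
#' @param lg linkage_group (markers with non-missing phase are used)
#' @param bm binary_markers
#' @return integer matrix markers x progeny (0/1/NA)
#' @export
phase_encode <- function(lg, bm) {
  mk <- lg$markers[!is.na(lg$markers$phase), , drop = FALSE]
  if (!nrow(mk)) stop("linkage group has no phased markers")
  x <- subset_binary(bm, mk$marker)$values
  flip <- mk$phase == 1L
  x[flip, ] <- 1L - x[flip, ]
  x
}

#' Two-point recombination fractions and LOD scores
#'
#' For phase-encoded rows, `rf = discordant / informative` pairs (capped at
#' 0.5) and the backcross two-point LOD is
#' `R log10(2 rf) + (n - R) log10(2 (1 - rf))` (with `n log10 2` at rf = 0).
#' Pairs with fewer than `min_pairs` informative progeny are missing.
#'
#' @param x phase-encoded matrix (markers x progeny, 0/1/NA)
#' @param min_pairs minimum informative progeny per pair
#' @return list of class `two_point`: `rf`, `lod`, `n` (informative counts),
#'   `R` (discordant counts); all symmetric matrices
#' @export
pairwise_rf <- function(x, min_pairs = 20) {
  a1 <- (x == 1L) & !is.na(x); a0 <- (x == 0L) & !is.na(x)
  storage.mode(a1) <- storage.mode(a0) <- "numeric"
  n <- tcrossprod(a1 + a0)
  R <- tcrossprod(a1, a0) + tcrossprod(a0, a1)
  rf <- pmin(R / n, 0.5)
  r_ <- pmax(pmin(R / n, 0.4999999), 0)
  lod <- R * log10(2 * pmax(r_, 1e-12)) + (n - R) * log10(2 * (1 - r_))
  lod[which(R == 0)] <- (n * log10(2))[which(R == 0)]
  lod[which(rf >= 0.5)] <- 0
  low <- n < min_pairs
  rf[low] <- NA_real_; lod[low] <- NA_real_
  diag(rf) <- 0; diag(lod) <- NA_real_
  dimnames(rf) <- dimnames(lod) <- dimnames(n) <- dimnames(R) <-
    list(rownames(x), rownames(x))
  structure(list(rf = rf, lod = lod, n = n, R = R), class = "two_point")
}

# all permutations of 1..n as a matrix (n! rows); n <= 7 in practice
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- .perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

# total obligate-crossover objective of an order: sum of adjacent discordant
# counts
.order_cost <- function(ord, R) {
  if (length(ord) < 2) return(0)
  sum(R[cbind(ord[-length(ord)], ord[-1])])
}

# sliding-window exhaustive polish minimizing adjacent discordant counts
.polish_order <- function(ord, R, window = 5, max_passes = 5) {
  m <- length(ord)
  if (m <= 2) return(ord)
  w <- min(window, m)
  pm <- .perms(w)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (s in seq_len(m - w + 1)) {
      idx <- s:(s + w - 1)
      seg <- ord[idx]
      left <- if (s > 1) ord[s - 1] else NA
      right <- if (s + w <= m) ord[s + w] else NA
      segcost <- function(perm) {
        o <- seg[perm]
        cost <- sum(R[cbind(o[-w], o[-1])])
        if (!is.na(left)) cost <- cost + R[left, o[1]]
        if (!is.na(right)) cost <- cost + R[o[w], right]
        cost
      }
      costs <- apply(pm, 1, segcost)
      best <- which.min(costs)
      if (costs[best] < costs[1] - 1e-12) {
        ord[idx] <- seg[pm[best, ]]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ord
}

#' Order markers of a linkage group with a minimum-spanning-tree method
#'
#' The complete graph on the markers is weighted by pairwise recombination
#' fraction (missing estimates count as 0.5); its minimum spanning tree is
#' computed and the weighted diameter path forms the backbone order.
#' Off-backbone markers are inserted next to their tree attachment point (on
#' the side adding the smaller adjacent rf), and the order is polished with
#' a sliding-window (default 5) exhaustive permutation search minimising
#' total obligate crossovers.  Markers with more than `missing_max` missing
#' genotypes are excluded before ordering; markers essentially unlinked to
#' every other (all rf near 0.5) are split off and reported.  The returned
#' orientation is arbitrary.
#'
#' @param x phase-encoded matrix of the LG (markers x progeny)
#' @param stats optional precomputed [pairwise_rf()] result for `x`
#' @param window polish window size
#' @param missing_max maximum missing fraction per marker (default 0.5)
#' @param unlinked_rf rf above which a marker counts as unlinked to all
#'   others (default 0.49)
#' @return character vector of ordered marker ids; attribute `"dropped"`
#'   lists excluded markers
#' @export
order_markers_mst <- function(x, stats = NULL, window = 5,
                              missing_max = 0.5, unlinked_rf = 0.49) {
  keep <- rowMeans(is.na(x)) <= missing_max
  dropped <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 markers to order")
  if (is.null(stats) || !identical(rownames(stats$rf), rownames(x)))
    stats <- pairwise_rf(x)
  rf <- stats$rf
  rf[is.na(rf)] <- 0.5
  # split off markers unlinked to everything
  linked <- apply(rf + diag(Inf, nrow(rf)), 1, min) < unlinked_rf
  if (any(!linked)) {
    dropped <- c(dropped, rownames(x)[!linked])
    x <- x[linked, , drop = FALSE]
    rf <- rf[linked, linked, drop = FALSE]
    if (nrow(x) < 3) stop("fewer than 3 linked markers")
  }
  ids <- rownames(rf)
  g <- igraph::graph_from_adjacency_matrix(rf + 1e-9, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tr <- igraph::mst(g)
  backbone <- as.integer(igraph::get_diameter(tr))
  ord <- backbone
  off <- setdiff(seq_along(ids), backbone)
  if (length(off)) {
    sp <- igraph::distances(tr, v = off, to = backbone, weights = NA)  # hops
    attach_at <- backbone[apply(sp, 1, which.min)]
    hops <- apply(sp, 1, min)
    for (k in order(hops)) {
      v <- off[k]; a <- attach_at[k]
      pos <- match(a, ord)
      # cost of inserting before vs after the attachment marker
      cost_at <- function(p) {
        lft <- if (p > 1) ord[p - 1] else NA
        rgt <- if (p <= length(ord)) ord[p] else NA
        add <- 0
        if (!is.na(lft)) add <- add + rf[lft, v]
        if (!is.na(rgt)) add <- add + rf[v, rgt]
        rem <- if (!is.na(lft) && !is.na(rgt)) rf[lft, rgt] else 0
        add - rem
      }
      p <- if (cost_at(pos) <= cost_at(pos + 1)) pos else pos + 1
      ord <- append(ord, v, after = p - 1)
    }
  }
  ord <- .polish_order(ord, stats$R[ids, ids][], window = window)
  out <- ids[ord]
  attr(out, "dropped") <- dropped
  out
}

#' Remove redundant and double-crossover-inducing markers from an order
#'
#' Co-segregating bins (adjacent rf exactly 0) are collapsed keeping the
#' marker with the fewest missing calls; interior markers that imply a
#' double crossover (flanking markers agree, focal marker differs) in more
#' than `dxo_max` of fully-observed progeny are removed; the retained set is
#' then re-polished once.
#'
#' @param ord ordered marker ids
#' @param x phase-encoded matrix containing them
#' @param dxo_max maximum double-crossover fraction (default 0.2)
#' @param window polish window for the final re-ordering
#' @return list with `order` (retained ordered ids) and `removed`
#'   (data.frame marker/reason)
#' @export
filter_ordered_markers <- function(ord, x, dxo_max = 0.2, window = 5) {
  removed <- data.frame(marker = character(0), reason = character(0))
  xo <- x[ord, , drop = FALSE]
  st <- pairwise_rf(xo, min_pairs = 1)
  # collapse rf-0 bins
  m <- length(ord)
  adj0 <- vapply(seq_len(m - 1), function(i) {
    isTRUE(st$rf[i, i + 1] == 0)
  }, TRUE)
  bin <- cumsum(c(TRUE, !adj0))
  keep <- vapply(split(seq_len(m), bin), function(ix) {
    ix[which.min(rowSums(is.na(xo[ix, , drop = FALSE])))]
  }, 0L)
  if (length(keep) < m)
    removed <- rbind(removed,
                     data.frame(marker = ord[-keep], reason = "redundant"))
  ord <- ord[sort(keep)]
  # double-crossover filter
  if (length(ord) >= 3) {
    xo <- x[ord, , drop = FALSE]
    m <- length(ord)
    frac <- rep(0, m)
    for (j in 2:(m - 1)) {
      a <- xo[j - 1, ]; b <- xo[j, ]; cc <- xo[j + 1, ]
      obs <- !is.na(a) & !is.na(b) & !is.na(cc)
      if (!any(obs)) next
      frac[j] <- sum(a[obs] == cc[obs] & b[obs] != a[obs]) / sum(obs)
    }
    bad <- frac > dxo_max
    if (any(bad)) {
      removed <- rbind(removed,
                       data.frame(marker = ord[bad], reason = "double_crossover"))
      ord <- ord[!bad]
    }
  }
  if (length(ord) >= 3) {
    st <- pairwise_rf(x[ord, , drop = FALSE], min_pairs = 1)
    ord <- ord[.polish_order(seq_along(ord), st$R, window = window)]
  }
  list(order = ord, removed = removed)
}

#' Build per-LG map positions from an order
#'
#' Positions are the cumulative Kosambi distances of adjacent recombination
#' fractions, starting at 0 cM.
#'
#' @param ord ordered marker ids
#' @param x phase-encoded matrix
#' @param min_pairs minimum informative progeny for an adjacent estimate
#' @param max_cM cap for unlinked adjacencies
#' @return list with `cM` (named positions), `rf` (adjacent fractions)
#' @export
map_positions <- function(ord, x, min_pairs = 10, max_cM = 50) {
  xo <- x[ord, , drop = FALSE]
  st <- pairwise_rf(xo, min_pairs = min_pairs)
  rf <- st$rf[cbind(seq_len(length(ord) - 1), seq_len(length(ord) - 1) + 1)]
  rf[is.na(rf)] <- 0.5
  d <- suppressWarnings(kosambi(rf, max_cM = max_cM))
  list(cM = stats::setNames(c(0, cumsum(d)), ord), rf = rf)
}

#' Assign each linkage group to a parent and standard name
#'
#' With progenitor genotypes, an LG belongs to the parent whose high-quality
#' calls at the LG's markers are majority-heterozygous (at a Pt marker the
#' informative parent is AB, the other AA).  Without progenitors, the up-to
#' two LGs of each chromosome receive provisional labels unknown-A /
#' unknown-B (largest first).  Chromosome labels come from the defining
#' chromosome (synteny) or the modal physical chromosome of the members
#' (de novo).  Female LGs are numbered 1..n_chrom by chromosome, male LGs
#' n_chrom+1..2*n_chrom.
#'
#' @param lgs list of linkage_group
#' @param sites data.frame of marker metadata (site_id, chrom)
#' @param progenitors optional data.frame from [identify_pt_markers()]
#'   (site_id plus one dosage column per progenitor) with columns named
#'   `mother` and `father`
#' @param n_chrom chromosome count used for numbering
#' @return list of linkage_group with `parent`, `chrom_label` and `lg_number`
#'   filled in
#' @export
assign_parent_and_name <- function(lgs, sites, progenitors = NULL,
                                   n_chrom = 19) {
  for (i in seq_along(lgs)) {
    lg <- lgs[[i]]
    if (is.na(lg$chrom_label)) {
      ch <- sites$chrom[match(lg$markers$marker, sites$site_id)]
      tab <- sort(table(ch), decreasing = TRUE)
      lg$chrom_label <- names(tab)[1]
    }
    if (!is.null(progenitors) &&
        all(c("mother", "father") %in% names(progenitors))) {
      idx <- match(lg$markers$marker, progenitors$site_id)
      gm_ <- progenitors$mother[idx]; gf <- progenitors$father[idx]
      het_m <- sum(gm_ == 1L, na.rm = TRUE); hom_m <- sum(gm_ != 1L, na.rm = TRUE)
      het_f <- sum(gf == 1L, na.rm = TRUE); hom_f <- sum(gf != 1L, na.rm = TRUE)
      score_m <- het_m - hom_m; score_f <- het_f - hom_f
      lg$parent <- if (score_m > score_f) "female"
      else if (score_f > score_m) "male"
      else { warning("parent tie for ", lg$lg_id); "unknown" }
    }
    lgs[[i]] <- lg
  }
  if (is.null(progenitors)) {
    for (ch in unique(vapply(lgs, `[[`, "", "chrom_label"))) {
      here <- which(vapply(lgs, `[[`, "", "chrom_label") == ch)
      here <- here[order(-vapply(here, function(j) nrow(lgs[[j]]$markers), 0L))]
      lab <- c("unknown-A", "unknown-B")
      for (k in seq_along(here))
        lgs[[here[k]]]$parent <- lab[min(k, 2)]
    }
  }
  for (i in seq_along(lgs)) {
    ch_num <- suppressWarnings(as.integer(lgs[[i]]$chrom_label))
    lgs[[i]]$lg_number <- if (is.na(ch_num)) NA_integer_
    else if (identical(lgs[[i]]$parent, "male")) n_chrom + ch_num
    else ch_num
  }
  lgs
}

#' Join two split linkage groups, choosing the phase orientation
#'
#' Both relative phase orientations of the second LG are tried; each
#' candidate merge is ordered and measured, and the orientation giving the
#' shorter total map is kept (joining phases in repulsion inflates the map).
#' The join is refused when even the shorter candidate exceeds the summed
#' individual lengths by more than `max_extra_cM`.
#'
#' @param lg_a,lg_b linkage_group objects with the same parent and
#'   chromosome label
#' @param bm binary_markers
#' @param max_extra_cM refusal threshold (default 100)
#' @param window polish window for ordering
#' @return joined linkage_group with attribute `"join_report"` (lengths of
#'   both orientations), or an error/warning when refused
#' @export
join_split_lgs <- function(lg_a, lg_b, bm, max_extra_cM = 100, window = 5) {
  if (identical(sort(lg_a$markers$marker), sort(lg_b$markers$marker)))
    stop("cannot join a linkage group to itself")
  if (!identical(lg_a$parent, lg_b$parent) ||
      !identical(lg_a$chrom_label, lg_b$chrom_label))
    stop("linkage groups must share parent and chromosome")
  len_of <- function(lg) {
    x <- phase_encode(lg, bm)
    ord <- order_markers_mst(x, window = window)
    max(map_positions(ord, x)$cM)
  }
  len_a <- len_of(lg_a); len_b <- len_of(lg_b)
  candidate <- function(flip) {
    mb <- lg_b$markers
    if (flip) mb$phase <- 1L - mb$phase
    mk <- rbind(lg_a$markers, mb)
    lg <- linkage_group(paste0(lg_a$lg_id, "+", lg_b$lg_id), mk,
                        parent = lg_a$parent, chrom_label = lg_a$chrom_label,
                        provenance = lg_a$provenance)
    x <- phase_encode(lg, bm)
    ord <- order_markers_mst(x, window = window)
    list(lg = lg, ord = ord, len = max(map_positions(ord, x)$cM))
  }
  keepo <- candidate(FALSE); flipo <- candidate(TRUE)
  best <- if (keepo$len <= flipo$len) keepo else flipo
  if (best$len > len_a + len_b + max_extra_cM) {
    warning("join refused: best orientation spans ", round(best$len, 1),
            " cM vs parts ", round(len_a + len_b, 1), " cM")
    return(NULL)
  }
  out <- best$lg
  out$markers <- out$markers[match(best$ord, out$markers$marker), , drop = FALSE]
  attr(out, "join_report") <- c(length_kept = best$len,
                                length_rejected = max(keepo$len, flipo$len),
                                length_a = len_a, length_b = len_b)
  out
}

#' Order and measure a set of linkage groups into a genetic map
#'
#' For each LG: phase-encode, MST-order, remove redundant and
#' double-crossover markers, and compute Kosambi positions.
#'
#' @param lgs list of linkage_group (phased)
#' @param bm binary_markers
#' @param window polish window
#' @param min_pairs minimum informative progeny for adjacent rf estimates
#' @return object of class `genetic_map`: list of per-LG entries
#'   (lg_id, parent, chrom_label, markers, phase, cM, rf) plus removal
#'   reports
#' @export
build_genetic_map <- function(lgs, bm, window = 5, min_pairs = 10) {
  entries <- lapply(lgs, function(lg) {
    x <- phase_encode(lg, bm)
    ord <- order_markers_mst(x, window = window)
    fl <- filter_ordered_markers(ord, x, window = window)
    mp <- map_positions(fl$order, x, min_pairs = min_pairs)
    ph <- lg$markers$phase[match(fl$order, lg$markers$marker)]
    list(lg_id = lg$lg_id, parent = lg$parent, chrom_label = lg$chrom_label,
         lg_number = lg$lg_number %||% NA_integer_,
         markers = fl$order, phase = stats::setNames(ph, fl$order),
         cM = mp$cM, rf = mp$rf, removed = fl$removed)
  })
  structure(entries, class = "genetic_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total map length per linkage group
#' @param map genetic_map
#' @return named numeric vector of LG lengths in cM
#' @export
map_lengths <- function(map) {
  vapply(map, function(e) max(e$cM), 0,
         USE.NAMES = FALSE) -> len
  stats::setNames(len, vapply(map, `[[`, "", "lg_id"))
}

#' Flatten a genetic map to a marker table
#'
#' @param x genetic_map
#' @param sites optional site metadata to append chrom/pos
#' @param ... unused
#' @return data.frame with site_id, lg, parent, phase, cM (and chrom, pos)
#' @export
as.data.frame.genetic_map <- function(x, sites = NULL, ...) {
  df <- do.call(rbind, lapply(x, function(e) {
    data.frame(site_id = e$markers, lg = e$lg_id,
               lg_number = e$lg_number %||% NA_integer_,
               parent = e$parent, phase = unname(e$phase),
               cM = unname(e$cM), row.names = NULL)
  }))
  if (!is.null(sites)) {
    i <- match(df$site_id, sites$site_id)
    df$chrom <- sites$chrom[i]; df$pos <- sites$pos[i]
  }
  df
}
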