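#' Pairwise Pearson correlation of binary marker rows
#'
#' Correlations are computed over pairwise-complete progeny; entries backed
#' by fewer than `min_pairs` complete pairs, and rows constant on the
#' pairwise-complete subset, are reported missing (small overlaps produce
#' spurious +/- 1 correlations).
#'
#' @param bm binary_markers
#' @param min_pairs minimum pairwise-complete progeny count
#' @return list of class `marker_correlation` with `markers`, `r` (symmetric
#'   matrix, unit diagonal) and `n_obs`
#' @export
binary_correlation_matrix <- function(bm, min_pairs = 20) {
  if (nrow(bm$sites) < 2) stop("need at least two markers")
  v <- t(bm$values)  # progeny x markers
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  n_obs <- crossprod(!is.na(v))
  r[n_obs < min_pairs] <- NA_real_
  diag(r) <- 1
  dimnames(r) <- dimnames(n_obs) <- list(bm$sites$site_id, bm$sites$site_id)
  structure(list(markers = bm$sites$site_id, r = r, n_obs = n_obs),
            class = "marker_correlation")
}

#' Topological overlap dissimilarity of an adjacency matrix
#'
#' For adjacency a in [0,1] (self-adjacency ignored), the topological
#' overlap between nodes i and j is
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu`; the returned dissimilarity is
#' `1 - TOM` with a zero diagonal.  Nodes sharing many strong neighbours are
#' close even when their direct adjacency is moderate, which is what makes
#' whole linkage groups cohere.
#'
#' @param adjacency symmetric numeric matrix with values in [0,1]
#' @return symmetric dissimilarity matrix, zero diagonal
#' @export
tom_distance <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  a[is.na(a)] <- 0
  if (any(a < 0 | a > 1)) stop("adjacency values must lie in [0, 1]")
  a <- (a + t(a)) / 2
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  d <- 1 - tom
  diag(d) <- 0
  pmin(pmax(d, 0), 1)
}

#' Cut an average-linkage dendrogram at a static height
#'
#' Builds the average-linkage (UPGMA) tree of the distance matrix, cuts it
#' at `cut_height`, dissolves groups smaller than `min_cluster_size` into
#' "unassigned" (label 0) and renumbers the surviving clusters 1..K by
#' decreasing size (ties broken by first member).  Deterministic for a given
#' input order.
#'
#' @param distance symmetric distance matrix (or the tree from a previous
#'   call, see `tree`)
#' @param cut_height dendrogram cut height in (0, 1)
#' @param min_cluster_size minimum retained group size (>= 2)
#' @param tree optionally a precomputed `hclust` tree for `distance`
#' @return integer vector of cluster labels (0 = unassigned), named by
#'   marker; attribute `"tree"` carries the hclust object
#' @export
cluster_static_cut <- function(distance, cut_height, min_cluster_size = 30,
                               tree = NULL) {
  stopifnot(cut_height > 0, cut_height < 1, min_cluster_size >= 2)
  if (is.null(tree))
    tree <- stats::hclust(stats::as.dist(distance), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_cluster_size])
  lab <- ifelse(raw %in% keep, raw, 0L)
  if (!any(lab > 0L)) {
    warning("no cluster reached the minimum size; all markers unassigned")
  } else {
    surv <- unique(lab[lab > 0L])
    sz <- tabulate(match(lab, surv), nbins = length(surv))
    ord <- surv[order(-sz, match(surv, lab))]
    lab <- ifelse(lab == 0L, 0L, match(lab, ord))
  }
  names(lab) <- tree$labels
  attr(lab, "tree") <- tree
  lab
}

#' Correlation-ratio filter for mis-assigned markers ("diff" filter)
#'
#' For each query marker, the mean correlation (squared when
#' `mode = "squared"`) with the members of every candidate group is
#' computed and ranked.  The verdict is `agree` when the marker's assigned
#' group ranks first and its mean is at least `diff` times the second-best
#' mean; `disagree` when the assigned group does not rank first; and
#' `unresolved` otherwise (first, but not by the required margin).  The
#' query itself is excluded from its group mean; empty groups are excluded
#' from the ranking.
#'
#' @param assignment named integer/character vector: assigned group per query
#'   marker
#' @param groups named list of group -> member marker ids
#' @param correlation marker_correlation covering queries and members
#' @param diff ratio threshold (default 2)
#' @param mode `"squared"` (r^2, group assignment) or `"signed"` (r, phasing)
#' @return data.frame with marker, assigned, verdict, best group and the two
#'   leading means
#' @export
diff_filter <- function(assignment, groups, correlation, diff = 2,
                        mode = c("squared", "signed")) {
  mode <- match.arg(mode)
  r <- correlation$r
  v <- if (mode == "squared") r * r else r
  qids <- names(assignment)
  if (is.null(qids)) stop("assignment must be named by marker id")
  gnames <- names(groups)
  gm_means <- matrix(NA_real_, length(qids), length(gnames),
                     dimnames = list(qids, gnames))
  for (g in gnames) {
    mem <- intersect(groups[[g]], rownames(r))
    if (!length(mem)) next
    block <- v[qids, mem, drop = FALSE]
    # exclude self-correlation from the marker's own group mean
    self <- intersect(qids, mem)
    block[cbind(match(self, qids), match(self, mem))] <- NA_real_
    gm_means[, g] <- rowMeans(block, na.rm = TRUE)
  }
  verdict <- character(length(qids))
  best_g <- character(length(qids)); m1 <- m2 <- rep(NA_real_, length(qids))
  for (i in seq_along(qids)) {
    mu <- gm_means[i, ]
    mu <- mu[is.finite(mu)]
    if (!length(mu)) { verdict[i] <- "unresolved"; next }
    o <- order(mu, decreasing = TRUE)
    best_g[i] <- names(mu)[o[1]]
    m1[i] <- mu[o[1]]
    m2[i] <- if (length(mu) > 1) mu[o[2]] else NA_real_
    if (best_g[i] != as.character(assignment[i])) {
      verdict[i] <- "disagree"
    } else if (is.na(m2[i]) || m2[i] <= 0 || m1[i] >= diff * m2[i]) {
      verdict[i] <- "agree"
    } else {
      verdict[i] <- "unresolved"
    }
  }
  data.frame(marker = qids, assigned = as.character(assignment),
             verdict = verdict, best_group = best_g,
             best_mean = m1, second_mean = m2, row.names = NULL)
}

#' Separate a linkage group into its two parental phases
#'
#' Within one LG, markers on the same parental haplotype are positively
#' correlated and markers on opposite haplotypes negatively; the adjacency
#' is therefore the correlation truncated at zero, from which a topological
#' overlap dissimilarity is clustered and cut.  The two largest clusters are
#' reported as phases 0 and 1 (largest first); any extra clustered markers
#' are left unassigned with a warning.
#'
#' @param marker_ids markers of the LG
#' @param bm binary_markers containing them
#' @param cut_height static cut height (default 0.9)
#' @param min_phase_size minimum phase cluster size (default 10; large
#'   chromosome-scale groups support 30)
#' @param min_pairs passed to [binary_correlation_matrix()]
#' @return data.frame marker/phase (0, 1 or NA); attribute `"phased"` FALSE
#'   when fewer than two clusters emerged
#' @export
phase_linkage_group <- function(marker_ids, bm, cut_height = 0.9,
                                min_phase_size = 10, min_pairs = 20) {
  sub <- subset_binary(bm, marker_ids)
  if (nrow(sub$sites) < 2 * min_phase_size)
    stop("linkage group too small to phase at min_phase_size = ", min_phase_size)
  cm <- binary_correlation_matrix(sub, min_pairs = min_pairs)
  adj <- pmax(cm$r, 0)
  adj[is.na(adj)] <- 0
  d <- tom_distance(adj)
  lab <- suppressWarnings(
    cluster_static_cut(d, cut_height, min_cluster_size = min_phase_size))
  n_cl <- length(unique(lab[lab > 0L]))
  phase <- rep(NA_integer_, length(marker_ids))
  names(phase) <- marker_ids
  if (n_cl < 2) {
    res <- data.frame(marker = marker_ids, phase = phase, row.names = NULL)
    attr(res, "phased") <- FALSE
    attr(res, "n_clusters") <- n_cl
    return(res)
  }
  phase[names(lab)[lab == 1L]] <- 0L
  phase[names(lab)[lab == 2L]] <- 1L
  if (n_cl > 2)
    warning(sum(lab > 2L), " marker(s) in extra phase clusters left unassigned")
  res <- data.frame(marker = marker_ids, phase = unname(phase), row.names = NULL)
  attr(res, "phased") <- TRUE
  attr(res, "n_clusters") <- n_cl
  res
}
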