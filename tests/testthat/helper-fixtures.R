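# Small in-code fixtures and independent oracles shared across tests.

# genotype matrix from a plain dosage matrix (progeny only unless roles given)
make_gm <- function(gt, gq = NULL, roles = NULL, chrom = "1") {
  gt <- as.matrix(gt)
  n_s <- nrow(gt); n_i <- ncol(gt)
  sites <- data.frame(chrom = rep(chrom, length.out = n_s),
                      pos = seq_len(n_s) * 1000L, major = "A", minor = "B")
  if (is.null(roles)) roles <- rep("progeny", n_i)
  samples <- data.frame(id = sprintf("I%02d", seq_len(n_i)), role = roles)
  genotype_matrix(sites, samples, gt, gq)
}

make_binary <- function(values, chrom = NULL, pos = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  sites <- data.frame(chrom = if (is.null(chrom)) rep("1", n) else chrom,
                      pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
                      major = "A", minor = "B")
  sites$site_id <- if (!is.null(rownames(values))) rownames(values)
  else paste0("S", sites$chrom, "_", sites$pos)
  v <- values
  rownames(v) <- sites$site_id
  structure(list(sites = sites,
                 progeny = sprintf("P%03d", seq_len(ncol(values))),
                 values = v),
            class = "binary_markers")
}

# brute-force topological overlap dissimilarity (double loop)
tom_oracle <- function(a) {
  a <- as.matrix(a); diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    d[i, j] <- 1 - (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  d
}

# exhaustive forward likelihood: sum over all 2^m hidden phase paths
hmm_oracle <- function(x, r, eps) {
  m <- nrow(x)
  states <- as.matrix(expand.grid(rep(list(0:1), m)))
  total <- 0
  for (j in seq_len(ncol(x))) {
    lik <- 0
    for (s in seq_len(nrow(states))) {
      z <- states[s, ]
      p <- 0.5
      for (i in seq_len(m - 1))
        p <- p * if (z[i] == z[i + 1]) 1 - r[i] else r[i]
      for (i in seq_len(m)) {
        if (is.na(x[i, j])) next
        p <- p * if (x[i, j] == z[i]) 1 - eps else eps
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# minimum over all orders of the total adjacent recombination fraction
exhaustive_best_order_cost <- function(rf) {
  n <- nrow(rf)
  perms <- ptmapr:::.perms(n)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    o <- perms[i, ]
    best <- min(best, sum(rf[cbind(o[-n], o[-1])]))
  }
  best
}

# adjusted Rand index between two labellings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
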