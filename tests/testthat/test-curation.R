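# build a one-LG genetic map entry directly from a phase-encoded matrix
entry_from <- function(x) {
  mp <- map_positions(rownames(x), x, min_pairs = 5)
  list(lg_id = "LG1", parent = "female", chrom_label = "1",
       lg_number = 1L, markers = rownames(x),
       phase = stats::setNames(rep(0L, nrow(x)), rownames(x)),
       cM = mp$cM, rf = mp$rf, removed = NULL)
}
map_from <- function(x) structure(list(entry_from(x)), class = "genetic_map")

test_that("HMM forward likelihood matches the exhaustive path sum", {
  set.seed(101)
  for (m in c(3, 6, 10, 12)) {
    x <- matrix(sample(c(0L, 1L, NA), m * 4, TRUE, prob = c(.45, .45, .1)), m)
    rownames(x) <- paste0("M", seq_len(m))
    r <- runif(m - 1, 0.01, 0.4)
    for (eps in c(0.01, 0.1)) {
      expect_equal(as.numeric(hmm_loglik(x, r, eps)), hmm_oracle(x, r, eps),
                   tolerance = 1e-8)
    }
  }
})

test_that("EM rf updates increase the likelihood and shrink inflated maps", {
  lg <- simulate_lg_binary(20, 200, spacing_cM = 4, epsilon = 0.05, seed = 103)
  x <- lg$values
  st <- pairwise_rf(x, min_pairs = 5)
  r0 <- st$rf[cbind(1:19, 2:20)]
  ll0 <- as.numeric(hmm_loglik(x, r0, 0.05))
  r1 <- ptmapr:::.hmm_rf_update(x, r0, 0.05)
  ll1 <- as.numeric(hmm_loglik(x, r1, 0.05))
  expect_gte(ll1, ll0)
  # error-corrected distances are shorter than raw, error-inflated ones
  expect_lt(sum(kosambi(r1)), sum(kosambi(r0)))
})

test_that("the genotyping error rate is recovered across planted values", {
  for (eps in c(0.01, 0.05, 0.1)) {
    lg <- simulate_lg_binary(30, 200, spacing_cM = 3, epsilon = eps,
                             seed = 107 + round(1000 * eps))
    est <- estimate_error_rate(lg$values)
    expect_lt(abs(est$eps_hat - eps), 0.02)
    expect_equal(max(est$loglik$loglik),
                 est$loglik$loglik[est$loglik$eps == est$eps_hat])
  }
  # noiseless data drive the estimate to the bottom of the grid
  lg0 <- simulate_lg_binary(15, 150, spacing_cM = 4, epsilon = 0, seed = 109)
  est0 <- estimate_error_rate(lg0$values)
  expect_equal(est0$eps_hat, min(curation_params()$error_prob_grid))
})

test_that("missing-data and crossover filters apply their exact thresholds", {
  lg <- simulate_lg_binary(10, 40, spacing_cM = 5, seed = 113)
  x <- lg$values
  x[1, 1:20] <- NA                      # exactly 50% missing -> removed (>=)
  x[2, 1:19] <- NA                      # 47.5% -> kept
  bm <- make_binary(x)
  map <- map_from(x)
  out <- filter_missing_and_crossovers(map, bm)
  expect_identical(out$removed_markers, rownames(x)[1])
  expect_false(rownames(x)[2] %in% out$removed_markers)
  # clean genome-scale map (crossover counts concentrated well above 0):
  # no individuals removed
  mats <- lapply(1:8, function(k) {
    m <- simulate_lg_binary(20, 40, spacing_cM = 5, seed = 113 + k)$values
    rownames(m) <- paste0("C", k, "_", rownames(m))
    m
  })
  big_bm <- make_binary(do.call(rbind, mats))
  entries <- lapply(mats, function(m) {
    e <- entry_from(m)
    e$lg_id <- rownames(m)[1]
    e
  })
  big_map <- structure(entries, class = "genetic_map")
  out_big <- filter_missing_and_crossovers(big_map, big_bm)
  expect_length(out_big$removed_individuals, 0)
  # an individual at exactly twice the mean is retained (strict >)
  xb <- rbind(M1 = c(0L, 0L, 0L, 0L),
              M2 = c(1L, 0L, 0L, 0L),
              M3 = c(0L, 0L, 0L, 0L),
              M4 = c(1L, 0L, 1L, 0L),
              M5 = c(0L, 0L, 0L, 0L))
  # crossover counts: 4, 0, 2, 0 -> mean 1.5, threshold 3: only P001 removed
  outb <- suppressWarnings(
    filter_missing_and_crossovers(suppressWarnings(map_from(xb)),
                                  make_binary(xb)))
  expect_identical(outb$removed_individuals, "P001")
})

test_that("crossover-excess individuals are removed with strict >2x mean", {
  mats <- lapply(1:8, function(k) {
    m <- simulate_lg_binary(20, 40, spacing_cM = 5, seed = 127 + k)$values
    rownames(m) <- paste0("C", k, "_", rownames(m))
    m
  })
  # plant one individual with alternating phases on one LG: ~19 extra
  # obligate crossovers on a family mean of ~7
  mats[[1]][, 1] <- rep(c(0L, 1L), 10)
  bm <- make_binary(do.call(rbind, mats))
  entries <- lapply(mats, function(m) {
    e <- entry_from(m); e$lg_id <- rownames(m)[1]; e
  })
  out <- filter_missing_and_crossovers(structure(entries,
                                                 class = "genetic_map"), bm)
  expect_identical(out$removed_individuals, "P001")
})

test_that("the drop-one scan removes planted noisy markers", {
  lg <- simulate_lg_binary(25, 250, spacing_cM = 2, seed = 131)
  x <- lg$values
  noisy <- x[12, ]
  flip <- sample(length(noisy), 25)      # 10% isolated flips
  noisy[flip] <- 1L - noisy[flip]
  x[12, ] <- noisy
  bm <- make_binary(x)
  entry <- entry_from(x)
  len_before <- max(entry$cM)
  sc <- drop_one_marker_scan(entry, bm, eps_hat = 0.001,
                             lod_threshold = 3)
  expect_true(rownames(x)[12] %in% sc$removed)
  expect_lt(max(sc$entry$cM), len_before - 2)
  # clean LG: nothing removed at the same threshold
  lgc <- simulate_lg_binary(25, 250, spacing_cM = 2, seed = 137)
  entc <- entry_from(lgc$values)
  scc <- drop_one_marker_scan(entc, make_binary(lgc$values),
                              eps_hat = 0.001, lod_threshold = 3)
  expect_length(scc$removed, 0)
  # the scan reports a value for every interior marker
  expect_equal(sum(!is.na(scc$scan$lod_diff)), nrow(lgc$values) - 2)
})

test_that("rippling restores a planted adjacent swap and never inflates", {
  lg <- simulate_lg_binary(15, 300, spacing_cM = 6, seed = 139)
  x <- lg$values
  swapped <- rownames(x)[c(1:7, 9, 8, 10:15)]
  xs <- x[swapped, ]
  bm <- make_binary(x)
  entry <- entry_from(xs)
  before <- obligate_crossovers(xs)
  fin <- ripple_and_finalize(entry, make_binary(xs), sites = NULL)
  after <- obligate_crossovers(ptmapr:::lg_matrix(fin$entry, make_binary(xs)))
  expect_lte(sum(after), sum(before))
  expect_identical(fin$entry$markers, rownames(x))   # swap undone
  # an already optimal order is a fixed point
  fin2 <- ripple_and_finalize(entry_from(x), bm, sites = NULL)
  expect_identical(fin2$entry$markers, rownames(x))
})

test_that("backwards LGs are inverted against physical positions", {
  lg <- simulate_lg_binary(12, 300, spacing_cM = 6, seed = 149)
  x <- lg$values[12:1, ]                  # reversed relative to physical pos
  bm <- make_binary(x)                    # pos increases with row index
  sites <- bm$sites
  sites$pos <- rev(sites$pos)             # physical order = original order
  fin <- ripple_and_finalize(entry_from(x), bm, sites = sites)
  expect_true(fin$inverted)
  expect_gt(stats::cor(fin$entry$cM,
                       sites$pos[match(fin$entry$markers, sites$site_id)]),
            0.99)
})

test_that("full curation shrinks error-inflated maps and keeps invariants", {
  lg <- simulate_lg_binary(30, 200, spacing_cM = 3, epsilon = 0.03, seed = 151)
  bm <- make_binary(lg$values)
  map <- map_from(lg$values)
  cur <- suppressWarnings(curate_map(map, bm))
  rep <- cur$report
  expect_lt(rep$final[["cM"]], rep$initial[["cM"]])
  stages <- rbind(rep$initial, rep$step1, rep$step2, rep$step3, rep$step4,
                  rep$final)
  expect_true(all(diff(stages[, "markers"]) <= 0))   # only removals
  for (e in cur$map) {
    expect_equal(unname(e$cM[1]), 0)
    expect_true(all(diff(e$cM) >= -1e-9))
  }
  # estimated error rate close to the planted one
  expect_lt(abs(rep$eps_hat[[1]] - 0.03), 0.02)
})
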