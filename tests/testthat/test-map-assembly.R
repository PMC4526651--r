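test_that("the Kosambi map function and its inverse are exact", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3))   # 27.465 cM
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(kosambi_inv(kosambi(r)), r, tolerance = 1e-12)
  expect_warning(d <- kosambi(0.5), "capped")
  expect_equal(d, 50)
  expect_error(kosambi(-0.1), "negative")
})

test_that("two-point rf and LOD match their closed forms", {
  x <- rbind(a = rep(c(0L, 1L), 10),
             b = rep(c(0L, 1L), 10),
             c = c(rep(c(0L, 1L), 9), 1L, 0L))
  st <- pairwise_rf(x, min_pairs = 5)
  expect_equal(st$rf[1, 2], 0)
  expect_equal(st$lod[1, 2], 20 * log10(2))  # ~ 6.02
  expect_equal(st$rf[1, 3], 2 / 20)          # 2 discordant of 20
  expect_equal(st$rf, t(st$rf))
  # independent rows at large n: rf ~ 0.5, LOD ~ 0
  set.seed(59)
  y <- rbind(p = sample(0:1, 2000, TRUE), q = sample(0:1, 2000, TRUE))
  sty <- pairwise_rf(y)
  expect_lt(abs(sty$rf[1, 2] - 0.5), 0.04)
  expect_lt(abs(sty$lod[1, 2]), 2)
  # informative counts below min_pairs are missing
  z <- rbind(u = c(1L, 0L, rep(NA, 8)), v = c(1L, 0L, rep(NA, 8)))
  expect_true(is.na(pairwise_rf(z, min_pairs = 5)$rf[1, 2]))
})

test_that("MST ordering recovers simulated orders", {
  # clean, well-spaced markers: exact recovery up to reversal
  lg <- simulate_lg_binary(6, 500, spacing_cM = 10, seed = 61)
  ord <- order_markers_mst(lg$values)
  ids <- rownames(lg$values)
  ord <- as.vector(ord)
  expect_true(identical(ord, ids) || identical(ord, rev(ids)))
  # three markers: the middle one is identified by the rf triangle
  lg3 <- simulate_lg_binary(3, 400, spacing_cM = 15, seed = 67)
  ord3 <- order_markers_mst(lg3$values)
  expect_equal(ord3[2], rownames(lg3$values)[2])
  # noisy 5-marker toy: total adjacent rf no worse than the exhaustive best
  lg5 <- simulate_lg_binary(5, 80, spacing_cM = 8, epsilon = 0.05, seed = 71)
  st5 <- pairwise_rf(lg5$values, min_pairs = 5)
  ord5 <- order_markers_mst(lg5$values)
  got <- sum(st5$rf[cbind(ord5[-5], ord5[-1])])
  expect_lte(got, exhaustive_best_order_cost(st5$rf) + 1e-9)
})

test_that("larger shuffled maps are recovered with high rank agreement", {
  lg <- simulate_lg_binary(40, 300, spacing_cM = 3, epsilon = 0.01,
                           missing_rate = 0.1, seed = 73)
  x <- lg$values[sample(40), ]
  ord <- order_markers_mst(x)
  truth_rank <- match(ord, rownames(lg$values))
  tau <- abs(stats::cor(seq_along(truth_rank), truth_rank,
                        method = "kendall"))
  expect_gte(tau, 0.98)
})

test_that("redundant and double-crossover markers are filtered", {
  lg <- simulate_lg_binary(8, 150, spacing_cM = 6, seed = 79)
  x <- lg$values
  # duplicate marker 4 with extra missing data: the copy must be dropped
  dup <- x[4, ]; dup[1:10] <- NA
  x2 <- rbind(x[1:4, , drop = FALSE], M999 = dup, x[5:8, , drop = FALSE])
  fl <- filter_ordered_markers(rownames(x2), x2)
  expect_true("M999" %in% fl$removed$marker)
  expect_false(rownames(x)[4] %in% fl$removed$marker)
  expect_identical(fl$removed$reason[fl$removed$marker == "M999"], "redundant")
  # planted marker with 30% isolated flips is removed as double crossover
  noisy <- x[5, ]
  flip <- sample(length(noisy), 45)
  noisy[flip] <- 1L - noisy[flip]
  x3 <- rbind(x[1:5, , drop = FALSE], M888 = noisy, x[6:8, , drop = FALSE])
  fl3 <- filter_ordered_markers(rownames(x3), x3)
  expect_true("M888" %in%
                fl3$removed$marker[fl3$removed$reason == "double_crossover"])
  # clean LG: nothing removed
  expect_equal(nrow(filter_ordered_markers(rownames(x), x)$removed), 0L)
})

test_that("map positions accumulate Kosambi distances from 0", {
  lg <- simulate_lg_binary(10, 400, spacing_cM = 5, seed = 83)
  mp <- map_positions(rownames(lg$values), lg$values)
  expect_equal(unname(mp$cM[1]), 0)
  expect_true(all(diff(mp$cM) >= 0))
  expect_equal(max(mp$cM), sum(kosambi(mp$rf)))      # conservation
  expect_lt(abs(max(mp$cM) - 45) / 45, 0.2)
})

test_that("parent assignment and naming follow progenitor heterozygosity", {
  bm <- make_binary(matrix(rep(c(1L, 0L), 30), 6), chrom = rep("2", 6))
  lgs <- list(linkage_group("x", data.frame(marker = bm$sites$site_id,
                                            phase = 0L)))
  prog <- data.frame(site_id = bm$sites$site_id,
                     mother = c(1L, 1L, 1L, 1L, NA, 0L),
                     father = c(0L, 0L, 0L, NA, 0L, 0L))
  out <- assign_parent_and_name(lgs, bm$sites, progenitors = prog,
                                n_chrom = 19)
  expect_identical(out[[1]]$parent, "female")
  expect_identical(out[[1]]$chrom_label, "2")
  expect_equal(out[[1]]$lg_number, 2L)
  prog2 <- prog; names(prog2)[2:3] <- c("father", "mother")
  out2 <- assign_parent_and_name(lgs, bm$sites, progenitors = prog2,
                                 n_chrom = 19)
  expect_identical(out2[[1]]$parent, "male")
  expect_equal(out2[[1]]$lg_number, 21L)
  # no progenitors: provisional labels
  out3 <- assign_parent_and_name(lgs, bm$sites, n_chrom = 19)
  expect_identical(out3[[1]]$parent, "unknown-A")
})

test_that("joining split LGs picks the orientation with the shorter map", {
  set.seed(89)
  lg <- simulate_lg_binary(30, 250, spacing_cM = 4, seed = 97)
  bm <- make_binary(lg$values)
  ids <- bm$sites$site_id
  a <- linkage_group("A", data.frame(marker = ids[1:15], phase = 0L),
                     parent = "female", chrom_label = "1")
  # second half handed over with flipped phase labels: the join must test
  # both orientations and keep the consistent (shorter) one
  b <- linkage_group("B", data.frame(marker = ids[16:30], phase = 1L),
                     parent = "female", chrom_label = "1")
  j <- join_split_lgs(a, b, bm)
  rep <- attr(j, "join_report")
  expect_lte(rep[["length_kept"]], rep[["length_rejected"]])
  # the kept orientation un-flips B so all encoded rows align: markers of B
  # must carry phase 0 in the joined group
  expect_true(all(j$markers$phase[j$markers$marker %in% ids[16:30]] == 0L))
  expect_error(join_split_lgs(a, a, bm), "itself")
})
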