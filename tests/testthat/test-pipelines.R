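# shared small family at saturating coverage for the two LG pipelines
family_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chrom = 3, n_pt_female = 30, n_pt_male = 30,
                        n_nonpt = 5, n_progeny = 150, mean_depth = 40,
                        depth_sdlog = 0, seed = 37)
      sim <- simulate_gbs_family(cfg)
      pt <- identify_pt_markers(sim$calls)
      cache <<- list(sim = sim, pt = pt)
    }
    cache
  }
})

test_that("chromosome grouping drops unanchored markers by pattern", {
  bm <- make_binary(matrix(rep(c(0L, 1L), 50), 4),
                    chrom = c("2", "200", "5", "999"))
  out <- assign_chromosome_groups(bm, random_pattern = "00$")
  expect_equal(out$audit[["random_chrom"]], 1L)
  expect_setequal(names(out$groups), c("2", "5", "999"))
  out2 <- assign_chromosome_groups(bm, random_pattern = "00$|^999$")
  expect_equal(out2$audit[["random_chrom"]], 2L)
  expect_error(assign_chromosome_groups(bm, random_pattern = "."),
               "no assembled")
})

test_that("the synteny pipeline recovers two phased LGs per chromosome", {
  fx <- family_fixture()
  bm <- fx$pt$binary
  syn <- suppressWarnings(build_synteny_lgs(bm))
  expect_equal(sum(syn$audit[c("random_chrom", "disagree", "unresolved",
                               "agree")]),
               syn$audit[["initial"]])
  expect_gt(syn$audit[["agree"]] / syn$audit[["initial"]], 0.95)
  expect_equal(length(syn$lgs), 6L)  # 3 chromosomes x 2 parents
  tr <- fx$sim$truth$markers
  for (lg in syn$lgs) {
    tl <- tr$true_lg[match(lg$markers$marker, tr$site_id)]
    expect_gte(max(table(tl)) / length(tl), 0.99)            # purity
    expect_equal(length(unique(stats::na.omit(lg$markers$phase))), 2L)
  }
  # every marker ends up in exactly one LG
  all_mk <- unlist(lapply(syn$lgs, function(l) l$markers$marker))
  expect_false(anyDuplicated(all_mk) > 0)
})

test_that("a marker mislabelled to another chromosome is caught", {
  fx <- family_fixture()
  bm <- fx$pt$binary
  victim <- which(bm$sites$chrom == "1")[1]
  bm$sites$chrom[victim] <- "3"
  syn <- suppressWarnings(build_synteny_lgs(bm))
  vid <- bm$sites$site_id[victim]
  expect_identical(syn$verdicts$verdict[syn$verdicts$marker == vid],
                   "disagree")
  expect_false(vid %in% unlist(lapply(syn$lgs, function(l) l$markers$marker)))
})

test_that("the de novo sweep selects a grid point resolving all LGs", {
  fx <- family_fixture()
  bm <- fx$pt$binary
  sw <- sweep_and_select(bm, min_sizes = c(20, 40), n_chrom = 3)
  expect_true(sw$selected_ok)
  expect_gte(sw$selected$n_lgs, 6)
  # n_lgs nonincreasing in min_cluster_size at fixed height
  for (h in unique(sw$grid$height)) {
    sub <- sw$grid[sw$grid$height == h, ]
    sub <- sub[order(sub$min_size), ]
    expect_true(all(diff(sub$n_lgs) <= 0))
  }
  # single grid point: selected or flagged, never an error
  sw1 <- sweep_and_select(bm, heights = 0.95, min_sizes = 20, n_chrom = 3)
  expect_equal(nrow(sw1$grid), 1L)
  # de novo LGs agree with the synteny partition on shared markers
  dn <- build_denovo_lgs(bm, sw)
  syn <- suppressWarnings(build_synteny_lgs(bm))
  lab_of <- function(lgs) {
    u <- unlist(lapply(seq_along(lgs),
                       function(i) stats::setNames(rep(i, nrow(lgs[[i]]$markers)),
                                                   lgs[[i]]$markers$marker)))
    u
  }
  a <- lab_of(dn$lgs); b <- lab_of(syn$lgs)
  shared <- intersect(names(a), names(b))
  expect_gte(adjusted_rand(a[shared], b[shared]), 0.95)
  # all LGs phase into exactly 2 phases
  nph <- vapply(dn$lgs,
                function(l) length(unique(stats::na.omit(l$markers$phase))),
                0L)
  expect_true(all(nph == 2L))
  expect_length(dn$atypical, 0)
})

test_that("a marker correlated with two LGs is removed as unresolved", {
  set.seed(157)
  lg1 <- simulate_lg_binary(20, 200, spacing_cM = 4, seed = 163)$values
  lg2 <- simulate_lg_binary(20, 200, spacing_cM = 4, seed = 167)$values
  # chimera: half its progeny signal from each LG
  chim <- ifelse(seq_len(200) <= 100, lg1[10, ], lg2[10, ])
  bm <- make_binary(rbind(lg1, chim = chim, lg2))
  sw <- sweep_and_select(bm, heights = c(0.95, 0.9), min_sizes = 10,
                         n_chrom = 1)
  dn <- build_denovo_lgs(bm, sw)
  cid <- bm$sites$site_id[21]
  vd <- dn$verdicts[dn$verdicts$marker == cid, ]
  if (nrow(vd)) expect_true(vd$verdict %in% c("unresolved", "disagree"))
  expect_false(cid %in% unlist(lapply(dn$lgs, function(l) l$markers$marker)))
})

test_that("MAF/MTF profiling separates normal and collapsed duplicate sites", {
  cfg <- sim_config(n_chrom = 2, n_pt_female = 40, n_pt_male = 40, n_nonpt = 0,
                    n_progeny = 250, mean_depth = 20, depth_sdlog = 0,
                    seq_error = 0, n_dup_loci = 12, seed = 173)
  sim <- simulate_gbs_family(cfg)
  dup <- sim$truth$duplicates
  norm <- setdiff(sim$calls$sites$site_id, dup)
  prof <- maf_mtf_profile(sim$calls, final_ids = norm, removed_ids = dup)
  st <- prof$stats
  m_norm <- st$mtf[st$status == "final_map"]
  m_dup <- st$mtf[st$status == "removed"]
  expect_lt(abs(mean(m_norm) - expected_mtf(1)), 0.01)
  expect_lt(abs(mean(m_dup) - expected_mtf(2)), 0.01)
  # MAF does not separate the two classes (the duplication hides at call level)
  expect_lt(abs(mean(st$maf[st$status == "removed"]) -
                  mean(st$maf[st$status == "final_map"])), 0.03)
  # zero minor reads -> MTF 0
  gm0 <- make_gm(matrix(0L, 1, 3))
  gm0$ad_major[] <- 10L
  expect_equal(maf_mtf_profile(gm0, character(0))$stats$mtf, 0)
})

test_that("windowed statistics conserve crossovers and find distortion", {
  fx <- family_fixture()
  bm <- fx$pt$binary
  syn <- suppressWarnings(build_synteny_lgs(bm))
  lgs <- assign_parent_and_name(syn$lgs, bm$sites,
                                progenitors = fx$pt$progenitors, n_chrom = 3)
  map <- build_genetic_map(lgs, bm)
  gm_pt <- subset_genotypes(progeny_genotypes(fx$sim$calls),
                            sites = match(bm$sites$site_id,
                                          fx$sim$calls$sites$site_id))
  ws <- windowed_genome_stats(gm_pt, map, bm, window = 1e6, slide = 1e6)
  xs <- lapply(map, ptmapr:::lg_matrix, bm = bm)
  total_xo <- sum(obligate_crossovers(xs))
  n_prog <- length(bm$progeny)
  expect_equal(sum(ws$windows$recomb_freq) * n_prog, total_xo)
  # uniform Pt simulation: no distortion regions
  expect_equal(nrow(ws$distortion), 0L)
  # planted distorted region: minor allele transmitted at 70:30
  set.seed(179)
  v <- matrix(rbinom(40 * 400, 1, 0.5), 40)
  v[11:20, ] <- matrix(rbinom(10 * 400, 1, 0.7), 10)
  gm_d <- make_gm(v)
  ws_d <- windowed_genome_stats(gm_d, window = 4000, slide = 4000,
                                maf_lo = 0.20, maf_hi = 0.30)
  # MAF here is v/2 (AB vs AA): 0.25 normally, 0.35 in the planted region
  expect_equal(nrow(ws_d$distortion), 1L)
  expect_lte(abs(ws_d$distortion$start - 11000), 4000)
  expect_lte(abs(ws_d$distortion$end - 21000), 4000)
})
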