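test_that("genotype_matrix enforces its invariants", {
  expect_error(make_gm(matrix(3L, 2, 2)), "0, 1, 2")
  gm <- make_gm(rbind(c(0, 1), c(1, NA)))
  expect_equal(dim(gm), c(2L, 2L))
  expect_error(genotype_matrix(data.frame(chrom = "1", pos = 0, major = "A",
                                          minor = "B"),
                               data.frame(id = "a", role = "progeny"),
                               matrix(0L, 1, 1)), "positions")
  expect_error(genotype_matrix(data.frame(chrom = "1", pos = 1, major = "A",
                                          minor = "A"),
                               data.frame(id = "a", role = "progeny"),
                               matrix(0L, 1, 1)), "differ")
  expect_error(make_gm(matrix(0L, 1, 2), roles = c("mother", "mother")),
               "at most one")
})

test_that("to_binary maps AB/AA/missing and rejects BB", {
  gm <- make_gm(rbind(c(1L, 0L, NA), c(1L, 1L, 1L)))
  bm <- to_binary(gm)
  expect_identical(unname(bm$values[1, ]), c(1L, 0L, NA))
  expect_identical(unname(bm$values[2, ]), c(1L, 1L, 1L))
  counts <- binary_counts(bm)
  expect_equal(counts$n1, c(1L, 3L))
  expect_equal(counts$n_missing, c(1L, 0L))
  gm$gt[1, 1] <- 2L
  expect_error(to_binary(gm), "BB")
})

test_that("binary row sums count minor-allele carriers", {
  set.seed(1)
  g <- matrix(0L, 1, 100)
  g[1, sample(100, 52)] <- 1L
  expect_equal(sum(to_binary(make_gm(g))$values), 52)
})

test_that("VCF writing round-trips calls, qualities, depths and flags", {
  cfg <- sim_config(n_chrom = 1, n_pt_female = 8, n_pt_male = 8, n_nonpt = 2,
                    n_progeny = 12, mean_depth = 5, seed = 2)
  sim <- simulate_gbs_family(cfg)
  gm <- sim$calls
  gm$flag[1, 1] <- "C"; gm$gt[1, 1] <- 1L
  gm$flag[2, 2] <- "M"; gm$gt[2, 2] <- NA_integer_
  p <- withr::local_tempfile(fileext = ".vcf")
  write_marker_vcf(gm, p)
  txt <- readLines(p)
  expect_true(any(grepl("^##fileformat=VCFv4", txt)))
  expect_true(any(grepl(":C$", unlist(strsplit(txt[grep("^[^#]", txt)[1]],
                                               "\t")))))
  back <- read_genotype_vcf(p, roles = c(mother = "mother",
                                         father = "father"))
  expect_identical(unname(back$gt), unname(gm$gt))
  expect_identical(unname(back$gq), unname(gm$gq))
  expect_identical(unname(back$ad_minor), unname(gm$ad_minor))
  expect_identical(unname(back$flag), unname(gm$flag))
  expect_identical(back$samples$role, gm$samples$role)
})

test_that("VCF reading handles the ref/alt dialect and degenerate inputs", {
  # allele 1 at frequency 0.7 across samples -> allele 1 becomes major,
  # 1/1 calls become AA
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("s", 1:5)), collapse = "\t"),
               paste(c("1", "100", ".", "A", "C", ".", ".", ".", "GT",
                       "1/1", "1/1", "1/1", "0/1", "0/0"), collapse = "\t"),
               paste(c("1", "200", ".", "G", "T,C", ".", ".", ".", "GT",
                       "0/1", "0/1", "0/1", "0/1", "0/1"), collapse = "\t")),
             p)
  expect_warning(gm <- read_genotype_vcf(p, allele_order = "ref_alt"),
                 "multi-allelic")
  expect_equal(nrow(gm$sites), 1L)  # multi-allelic site skipped
  expect_identical(gm$sites$major, "C")
  expect_identical(gm$sites$minor, "A")
  expect_identical(unname(gm$gt[1, ]), c(0L, 0L, 0L, 1L, 2L))
  expect_true(all(gm$gq == 0))  # absent GQ recorded as 0

  # header-only VCF from an empty site list
  empty <- subset_genotypes(make_gm(matrix(0L, 2, 2)), sites = integer(0))
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_marker_vcf(empty, p2)
  expect_false(any(grepl("^[^#]", readLines(p2))))
})

test_that("csvsr cross files round-trip and use the declared alphabets", {
  bm <- make_binary(rbind(c(1L, 0L, NA), c(0L, 1L, 1L)))
  map <- data.frame(site_id = bm$sites$site_id, lg = "1", parent = "female",
                    phase = c(0L, 1L), cM = c(0, 12.345))
  p <- withr::local_tempfile(fileext = ".csv")
  write_crossfile(map, bm, p, format = "BC")
  back <- read_crossfile(p)
  expect_identical(back$markers$marker, map$site_id)
  expect_equal(back$markers$cM, map$cM, tolerance = 1e-3)
  expect_identical(unname(back$geno[1, ]), c("H", "A", "-"))
  expect_identical(unname(back$geno[2, ]), c("A", "H", "H"))

  ph <- data.frame(id = bm$progeny, sex = c(1, 0, 1))
  write_crossfile(map, bm, p, format = "FOURWAY", phenotypes = ph)
  back4 <- read_crossfile(p)
  expect_identical(back4$phenotypes$sex, c("1", "0", "1"))
  # phase 0 marker, carrier -> maternal haplotype A (code 5); phase 1 marker,
  # carrier -> haplotype B (code 6)
  expect_identical(unname(back4$geno[1, ]), c("5", "6", "-"))
  expect_identical(unname(back4$geno[2, ]), c("5", "6", "6"))
  expect_error(write_crossfile(map, subset_binary(bm, 1L), p), "absent")
})

test_that("read/write is the identity on random call matrices", {
  set.seed(9)
  for (rep in 1:3) {
    n_s <- sample(3:12, 1); n_i <- sample(2:8, 1)
    gt <- matrix(sample(c(0:2, NA), n_s * n_i, TRUE), n_s)
    gq <- matrix(sample(0:99, n_s * n_i, TRUE), n_s)
    gq[is.na(gt)] <- 0L
    gm <- make_gm(gt, gq)
    gm$flag[] <- sample(c("N", "M", "E"), n_s * n_i, TRUE)
    gm$flag[is.na(gm$gt)] <- sample(c("M", "E"), sum(is.na(gm$gt)), TRUE)
    gm$flag[!is.na(gm$gt)] <- "N"
    p <- withr::local_tempfile(fileext = ".vcf")
    write_marker_vcf(gm, p)
    back <- read_genotype_vcf(p)
    expect_identical(unname(back$gt), unname(gm$gt))
    expect_identical(unname(back$gq), unname(gm$gq))
    expect_identical(unname(back$flag), unname(gm$flag))
  }
})
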