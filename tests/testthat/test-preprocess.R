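test_that("allelic-primitive decomposition follows the filtering rules", {
  v <- tibble::tibble(chrom = "2",
                      pos = c(10, 30, 50, 100),
                      ref = c("AT", "A", "C", "G"),
                      alt = c("GC", "AGG", "T", "A"))
  out <- decompose_variants(v, radius = 2)
  # MNP AT->GC becomes two SNP primitives at 10 and 11
  expect_true(all(c(10, 11) %in% out$pos))
  # the insertion at 30 is removed; SNPs at 50 and 100 are far away and kept
  expect_setequal(out$pos, c(10, 11, 50, 100))
  expect_equal(attr(out, "log")[["non_snp"]], 1)

  # a SNP 1 bp from a deletion is dropped (within 2 bases of a non-SNP)
  v2 <- tibble::tibble(chrom = "2", pos = c(20, 24),
                       ref = c("ATT", "C"), alt = c("A", "G"))
  out2 <- decompose_variants(v2, radius = 2)
  expect_equal(nrow(out2), 0) # deletion spans 20-22, SNP at 24 within 2 bp
  expect_equal(attr(out2, "log")[["near_non_snp"]], 1)

  # multiallelic SNPs after decomposition are dropped
  v3 <- tibble::tibble(chrom = "2", pos = c(5, 5), ref = "A",
                       alt = c("C", "G"))
  out3 <- decompose_variants(v3)
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "log")[["multiallelic"]], 2)
})

test_that("genotype filters apply the depth and balance thresholds", {
  gt <- tidyr::expand_grid(chrom = "2", pos = as.numeric(1:40),
                           sample = c("s1", "s2"))
  set.seed(1)
  gt$gt <- "0/1"
  gt$dp <- rpois(nrow(gt), 30)
  gt$rpl <- pmax(gt$dp - 2, 0)
  gt$rpr <- 2L
  gt$saf <- 2L
  gt$sar <- 2L
  gt$dp[1] <- 7 # below the depth floor of 8
  gt$dp[2] <- 500 # far above mean + 2 sd
  gt$rpl[3] <- 0 # read placement balance violated
  out <- filter_genotypes(gt, filter_policy())
  expect_true(all(is.na(out$gt[1:3])))
  expect_false(anyNA(out$gt[-(1:3)]))

  # idempotence: filtering twice equals filtering once
  out2 <- filter_genotypes(out, filter_policy())
  expect_equal(out2$gt, out$gt)

  # monotonicity: stricter thresholds never increase callable genotypes
  stricter <- filter_genotypes(gt, filter_policy(min_depth = 25))
  expect_lte(sum(!is.na(stricter$gt)), sum(!is.na(out$gt)))

  # band mode also applies a data-driven lower bound
  band <- filter_genotypes(gt, filter_policy(dp_mode = "band",
                                             min_depth = 0))
  expect_lte(sum(!is.na(band$gt)), sum(!is.na(out$gt)) + 3)

  # strict handling of absent FORMAT fields
  expect_error(filter_genotypes(gt[, c("chrom", "pos", "sample", "gt")],
                                filter_policy(on_missing = "error")),
               "absent")
})

test_that("preprocess_variants carries MNP genotypes to primitives", {
  v <- tibble::tibble(chrom = "2", pos = 10, ref = "AT", alt = "GC")
  gt <- tibble::tibble(chrom = "2", pos = 10,
                       sample = c("s1", "s2"), gt = c("0/1", "1/1"),
                       dp = c(30, 30), rpl = c(15, 15), rpr = c(15, 15),
                       saf = c(15, 15), sar = c(15, 15))
  res <- preprocess_variants(v, gt)
  expect_setequal(res$variants$pos, c(10, 11))
  expect_equal(nrow(res$genotypes), 4) # 2 primitives x 2 samples
  expect_equal(sort(unique(res$genotypes$pos)), c(10, 11))
})

test_that("site-class masking equals a per-base oracle", {
  expect_equal(
    site_class_mask(tibble::tibble(chrom = "2", start = 0, end = 100),
                    tibble::tibble(chrom = "2", start = 50, end = 60)),
    tibble::tibble(chrom = "2", start = c(0, 60), end = c(50, 100)))

  # repeat covering the whole class leaves nothing
  empty <- site_class_mask(tibble::tibble(chrom = "2", start = 10, end = 20),
                           tibble::tibble(chrom = "2", start = 0, end = 50))
  expect_equal(nrow(empty), 0)

  # randomized toys against brute-force per-base set difference
  set.seed(42)
  for (i in 1:10) {
    mk <- function(n) {
      s <- sort(sample(0:9900, n))
      tibble::tibble(chrom = "z", start = s,
                     end = s + sample(1:80, n, replace = TRUE))
    }
    x <- mk(12)
    y <- mk(8)
    got <- site_class_mask(x, y)
    expect_equal(iv_positions(got), brute_force_setdiff(x, y))
  }

  expect_error(
    site_class_mask(tibble::tibble(chrom = "2", start = 0, end = 100),
                    chrom_lengths = c("2" = 50)),
    "beyond")
})
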