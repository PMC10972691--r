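test_that("dataset regeneration under a fixed seed is identical", {
  sc <- small_scenario(len = 20000, n_a = 2, n_b = 2, seed = 5)
  ds1 <- sim_dataset(sc)
  ds2 <- sim_dataset(sc)
  expect_identical(ds1$variants, ds2$variants)
  expect_identical(ds1$genotypes, ds2$genotypes)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dataset(ds1, dir1)
  write_dataset(ds2, dir2)
  expect_identical(readLines(file.path(dir1, "synthetic.vcf")),
                   readLines(file.path(dir2, "synthetic.vcf")))
})

test_that("zero mutation rate yields zero variants; zero-length chromosome errors", {
  sc <- small_scenario(len = 20000, n_a = 2, n_b = 2, seed = 2, mu = 0)
  ds <- sim_dataset(sc)
  expect_equal(nrow(ds$variants), 0)

  sc2 <- small_scenario(seed = 1)
  sc2$chromosomes$length[1] <- 0
  expect_error(sim_dataset(sc2), "zero-length")
})

test_that("DIV divergence and diversity match the structured-coalescent closed forms", {
  pars <- pars_sympatric_im()
  sc <- sim_scenario(
    chromosomes = tibble::tibble(chrom = "2", length = 512000,
                                 class = "autosome"),
    inversions = default_inversions()[0, ],
    params = tibble::tibble(partition = "auto_col", ne_a = pars$ne_a,
                            ne_b = pars$ne_b, ne_anc = pars$ne_anc,
                            t = pars$t, m = 0),
    n_a = 1, n_b = 1, seed = 3)
  ds <- sim_dataset(sc)
  bc <- block_counts(ds)
  st <- partition_stats(bc)
  mu <- sc$mu

  dxy_exp <- 2 * mu * ET_cross(pars$ne_anc, pars$t)
  se_dxy <- sd((0.5 * (bc$hetA + bc$hetB + bc$hetAB) + bc$fixed) / 64) /
    sqrt(nrow(bc))
  expect_lt(abs(st$dxy - dxy_exp), 3 * se_dxy)

  pia_exp <- 2 * mu * ET_within(pars$ne_a, pars$ne_anc, pars$t)
  pib_exp <- 2 * mu * ET_within(pars$ne_b, pars$ne_anc, pars$t)
  se_pa <- sd((bc$hetA + bc$hetAB) / 64) / sqrt(nrow(bc))
  se_pb <- sd((bc$hetB + bc$hetAB) / 64) / sqrt(nrow(bc))
  expect_lt(abs(st$pi_a - pia_exp), 3 * se_pa)
  expect_lt(abs(st$pi_b - pib_exp), 3 * se_pb)
})

test_that("within-species diversity matches theta = 4 Ne mu when the split is old", {
  # with t >> Ne the daughter population is effectively stationary
  ne <- 4e5
  sc <- sim_scenario(
    chromosomes = tibble::tibble(chrom = "2", length = 1060000,
                                 class = "autosome"),
    inversions = default_inversions()[0, ],
    params = tibble::tibble(partition = "auto_col", ne_a = ne, ne_b = ne,
                            ne_anc = ne, t = 40 * ne, m = 0),
    n_a = 1, n_b = 1, seed = 4)
  ds <- sim_dataset(sc)
  bc <- block_counts(ds)
  st <- partition_stats(bc)
  theta <- 4 * ne * sc$mu
  se_pa <- sd((bc$hetA + bc$hetAB) / 64) / sqrt(nrow(bc))
  expect_gt(nrow(bc), 1e4)
  expect_lt(abs(st$pi_a - theta), 3 * se_pa)
})

test_that("older inversions show higher divergence than the colinear background", {
  inv <- tibble::tibble(chrom = "2", start = 10000, end = 30000,
                        carrier = "B")
  chroms <- tibble::tibble(chrom = "2", length = 40000, class = "autosome")
  pars <- tibble::tibble(
    partition = c("auto_col", "inv_2"),
    ne_a = 5e5, ne_b = 5e5, ne_anc = 1e6,
    t = c(2e6, 5e6), m = 0)
  diffs <- purrr::map_dbl(1:20, function(s) {
    sc <- sim_scenario(chromosomes = chroms, inversions = inv, params = pars,
                       n_a = 1, n_b = 1, seed = 100 + s)
    st <- partition_stats(block_counts(sim_dataset(sc)))
    st$dxy[st$partition == "inv_2"] - st$dxy[st$partition == "auto_col"]
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("a VCF written from a dataset reads back identically", {
  sc <- small_scenario(len = 20000, n_a = 2, n_b = 2, seed = 8)
  ds <- sim_dataset(sc)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  rt <- read_variants(file.path(dir, "synthetic.vcf"))
  expect_equal(rt$variants$pos, ds$variants$pos)
  expect_equal(rt$variants$ref, ds$variants$ref)
  g1 <- dplyr::arrange(rt$genotypes, chrom, pos, sample)
  g2 <- dplyr::arrange(ds$genotypes, chrom, pos, sample)
  expect_equal(g1$gt, g2$gt)
})
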