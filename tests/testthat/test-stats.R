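test_that("partition statistics evaluate the documented formulas", {
  # one block with one hetA site and one fixed difference (l = 64):
  # d_xy = 1.5/64 (brute force over the four heterospecific haplotype
  # pairs), pi_A = 1/64, pi_B = 0, Hudson F_ST = 1 - (1/128)/(1.5/64) = 2/3
  bc <- tibble::tibble(partition = "p", hetA = 1L, hetB = 0L, hetAB = 0L,
                       fixed = 1L)
  st <- partition_stats(bc, block_length = 64)
  expect_equal(st$dxy, 1.5 / 64)
  expect_equal(st$pi_a, 1 / 64)
  expect_equal(st$pi_b, 0)
  expect_equal(st$fst, 2 / 3)

  # monomorphic data: zero divergence, F_ST undefined
  st0 <- partition_stats(tibble::tibble(partition = "p", hetA = 0L,
                                        hetB = 0L, hetAB = 0L, fixed = 0L),
                         block_length = 64)
  expect_equal(st0$dxy, 0)
  expect_true(is.na(st0$fst))

  # d_xy is symmetric in the species labels; F_ST <= 1 always
  set.seed(2)
  cnt <- tibble::tibble(partition = "p",
                        hetA = rpois(50, 1), hetB = rpois(50, 1),
                        hetAB = rpois(50, 0.3), fixed = rpois(50, 1))
  sw <- dplyr::rename(cnt, hetA = hetB, hetB = hetA)
  s1 <- partition_stats(cnt, 64)
  s2 <- partition_stats(sw, 64)
  expect_equal(s1$dxy, s2$dxy)
  expect_equal(s1$fst, s2$fst)
  expect_lte(s1$fst, 1)
  # F_ST = 1 iff only fixed differences
  sf <- partition_stats(tibble::tibble(partition = "p", hetA = 0L,
                                       hetB = 0L, hetAB = 0L, fixed = 3L),
                        64)
  expect_equal(sf$fst, 1)
})

test_that("sliding windows advance by step and drop partial tails", {
  mk <- function(n, dxy_counts) {
    tibble::tibble(chrom = "c1", start = (seq_len(n) - 1) * 64,
                   end = seq_len(n) * 64, hetA = 0L, hetB = 0L, hetAB = 0L,
                   fixed = dxy_counts)
  }
  # 10,000 blocks, window 5,000, step 500 -> floor((10000-5000)/500)+1 = 11
  w <- sliding_window_dxy(mk(10000, 1L), window = 5000, step = 500,
                          block_length = 64)
  expect_equal(nrow(w), 11)
  # exactly one window when blocks == window
  w1 <- sliding_window_dxy(mk(5000, 1L), window = 5000, step = 500,
                           block_length = 64)
  expect_equal(nrow(w1), 1)
  # constant blocks give constant windows
  expect_true(all(w$dxy == 1 / 64))
  # fewer blocks than a window -> empty scan
  expect_equal(nrow(sliding_window_dxy(mk(10, 1L), window = 100, step = 10,
                                       block_length = 64)), 0)

  # weighted check: the mean over non-overlapping windows equals the
  # partition mean
  set.seed(3)
  cnts <- rpois(6000, 1.2)
  bc <- mk(6000, cnts)
  nw <- sliding_window_dxy(bc, window = 1000, step = 1000, block_length = 64)
  expect_equal(mean(nw$dxy), mean(cnts / 64))
})

test_that("G-test matches a likelihood-ratio oracle and handles edge cases", {
  # perfectly balanced table: no association
  g0 <- gtest_2x2(c(10, 10, 10, 10))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)

  # independent oracle: G = 2 * N * mutual information (entropy route)
  g_lrt <- function(m) {
    n <- sum(m)
    h <- function(p) {
      p <- p[p > 0]
      -sum(p * log(p))
    }
    2 * n * (h(rowSums(m) / n) + h(colSums(m) / n) - h(m / n))
  }
  set.seed(4)
  for (i in 1:20) {
    m <- matrix(rpois(4, 40) + 1, 2, 2)
    expect_equal(gtest_2x2(m)$statistic, g_lrt(m), tolerance = 1e-10)
  }
  g <- gtest_2x2(matrix(c(20, 10, 10, 20), 2, 2))
  expect_equal(g$statistic, g_lrt(matrix(c(20, 10, 10, 20), 2, 2)))
  expect_equal(g$p_value, pchisq(g$statistic, 1, lower.tail = FALSE))

  # selected-gene enrichment counts: the standard formula gives ~0.25,
  # documented as differing from the published 0.159
  gsel <- gtest_2x2(c(45, 1952, 112, 5314))
  expect_equal(gsel$statistic, g_lrt(matrix(c(45, 1952, 112, 5314), 2, 2,
                                            byrow = TRUE)))
  expect_gt(gsel$p_value, 0.05)

  expect_error(gtest_2x2(c(0, 0, 5, 5)), "marginal")
  expect_error(gtest_2x2(c(-1, 2, 3, 4)), "non-negative")
})
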