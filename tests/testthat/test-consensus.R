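test_that("noise-free caller tables contain exactly the true calls", {
  sc <- sim_scenario(seed = 10)
  calls <- sim_sv_calls(sc, jitter_sd = 0, fn_rate = 0, fp_rate = 0)
  n_a <- sum(sc$samples$species == "A")
  n_b <- sum(sc$samples$species == "B")
  exp_n <- sum(ifelse(sc$inversions$carrier == "A", n_a, n_b))
  expect_equal(nrow(calls$caller1), exp_n)
  expect_equal(nrow(calls$caller2), exp_n)
  expect_true(all(calls$caller1$type == "INV"))

  # false-negative rate of one empties the tables
  empty <- sim_sv_calls(sc, jitter_sd = 0, fn_rate = 1, fp_rate = 0)
  expect_equal(nrow(empty$caller1), 0)

  expect_error(sim_sv_calls(sc, fn_rate = 2), "rates")
})

test_that("jittered breakpoints stay near truth and are reproducible", {
  sc <- sim_scenario(seed = 11)
  c1 <- sim_sv_calls(sc, jitter_sd = 200, fn_rate = 0, fp_rate = 0, seed = 5)
  c2 <- sim_sv_calls(sc, jitter_sd = 200, fn_rate = 0, fp_rate = 0, seed = 5)
  expect_identical(c1, c2)
  truth <- sc$inversions
  for (i in seq_len(nrow(truth))) {
    sub <- c1$caller1[c1$caller1$chrom == truth$chrom[i] &
                        abs(c1$caller1$start - truth$start[i]) < 5000, ]
    expect_true(all(abs(sub$start - truth$start[i]) <= 3 * 200 + 1))
    expect_true(all(abs(sub$end - truth$end[i]) <= 3 * 200 + 1))
  }
})

test_that("merging clusters identical and jittered calls correctly", {
  base <- tibble::tibble(chrom = "4", start = 1e6, end = 2e6, type = "INV",
                         sample = "s1", species = "A", caller = "caller1")
  dup <- base
  dup$caller <- "caller2"
  m <- merge_sv_calls(list(base, dup))
  cl <- attr(m, "clusters")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_callers, 2)

  # offset by 2x tolerance -> separate clusters
  far <- dup
  far$start <- far$start + 2000
  far$end <- far$end + 2000
  m2 <- merge_sv_calls(list(base, far), tol = 1000)
  expect_equal(nrow(attr(m2, "clusters")), 2)

  # jittered synthetic truth recovered by clustering (brute-force match)
  sc <- sim_scenario(seed = 12)
  calls <- sim_sv_calls(sc, jitter_sd = 150, fn_rate = 0, fp_rate = 0,
                        seed = 2)
  m3 <- merge_sv_calls(calls, tol = 1000, min_overlap = 0.8)
  cl3 <- attr(m3, "clusters")
  expect_equal(nrow(cl3), nrow(sc$inversions))
  matched <- purrr::map_int(seq_len(nrow(sc$inversions)), function(i) {
    sum(cl3$chrom == sc$inversions$chrom[i] &
          abs(cl3$start - sc$inversions$start[i]) < 1000 &
          abs(cl3$end - sc$inversions$end[i]) < 1000)
  })
  expect_true(all(matched == 1))
})

test_that("the fixed-inversion filter applies every rule", {
  mk_cluster <- function(n_a, n_b, size = 7.2e6, callers = c("caller1",
                                                             "caller2")) {
    smp <- c(sprintf("a%02d", seq_len(n_a)), sprintf("b%02d", seq_len(n_b)))
    spc <- rep(c("A", "B"), c(n_a, n_b))
    purrr::map_dfr(callers, function(cl) {
      tibble::tibble(chrom = "X", start = 1e6, end = 1e6 + size,
                     type = "INV", sample = smp, species = spc, caller = cl)
    })
  }
  # study-like X inversion: 7.2 Mb, 10/12 A samples, absent in B
  m <- merge_sv_calls(mk_cluster(10, 0))
  keep <- consensus_inversions(m)
  expect_equal(nrow(keep), 1)
  expect_equal(keep$species, "A")
  expect_equal(keep$size, 7.2e6)

  # too small
  m2 <- merge_sv_calls(mk_cluster(10, 0, size = 4e5))
  expect_equal(nrow(consensus_inversions(m2)), 0)
  # not enough carriers (8 of 12 < 9)
  m3 <- merge_sv_calls(mk_cluster(8, 0))
  expect_equal(nrow(consensus_inversions(m3)), 0)
  # present in both species beyond tolerance -> not species-specific
  m4 <- merge_sv_calls(mk_cluster(10, 7))
  expect_equal(nrow(consensus_inversions(m4)), 0)
  # single-caller support is insufficient
  m5 <- merge_sv_calls(mk_cluster(10, 0, callers = "caller1"))
  expect_equal(nrow(consensus_inversions(m5)), 0)
  # impossible support raises
  m6 <- merge_sv_calls(mk_cluster(13, 0))
  expect_error(consensus_inversions(m6), "cohort")
})

test_that("the filter is order- and caller-label-invariant and monotone", {
  sc <- sim_scenario(seed = 14)
  calls <- sim_sv_calls(sc, jitter_sd = 100, fn_rate = 0.05, fp_rate = 0.05,
                        seed = 3)
  all_calls <- dplyr::bind_rows(calls)
  res1 <- consensus_inversions(merge_sv_calls(all_calls), min_size = 1e4)
  # shuffled input
  set.seed(1)
  res2 <- consensus_inversions(
    merge_sv_calls(all_calls[sample(nrow(all_calls)), ]), min_size = 1e4)
  expect_equal(res1, res2)
  # caller labels swapped
  sw <- all_calls
  sw$caller <- ifelse(sw$caller == "caller1", "caller2", "caller1")
  res3 <- consensus_inversions(merge_sv_calls(sw), min_size = 1e4)
  expect_equal(dplyr::select(res1, -callers), dplyr::select(res3, -callers))
  # raising thresholds never adds inversions
  res_strict <- consensus_inversions(merge_sv_calls(all_calls),
                                     min_size = 1e4,
                                     min_carriers = c(A = 12, B = 9),
                                     max_other = 0)
  expect_lte(nrow(res_strict), nrow(res1))
})
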