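fit_quick <- list(n_starts = 1, free = c("t", "m"),
                  control = list(maxit = 300, reltol = 1e-9))

test_that("bootstrap p-values respect their bounds", {
  pars <- pars_intraspecific_div()
  tal <- sim_tally("div", pars, 2000, kmax = 1, seed = 5)
  fd <- fit_bsfs(tal, "div", init = pars, n_starts = 1, free = "t",
                 control = list(maxit = 200))
  bt0 <- parametric_bootstrap(fd, observed_delta = 0, n_reps = 6,
                              n_blocks = 2000, n_chunks = 2000, seed = 2,
                              fit_args = fit_quick)
  # the null deltas are all >= 0, so an observed delta of 0 cannot be beaten
  expect_equal(bt0$p_value, 1)
  bt_big <- parametric_bootstrap(fd, observed_delta = 1e6, n_reps = 6,
                                 n_blocks = 2000, n_chunks = 2000, seed = 2,
                                 fit_args = fit_quick)
  # the add-one estimator never returns zero
  expect_equal(bt_big$p_value, 1 / (bt_big$n_eff + 1))
  expect_gt(bt_big$p_value, 0)
  expect_equal(bt_big$n_eff, 6)
  expect_true(all(bt_big$null$delta >= 0))
  gl <- glance(bt_big)
  expect_equal(gl$p_value, bt_big$p_value)
})

test_that("inversion null test validates inputs and returns calibrated structure", {
  pars <- list(ne_a = 1e5, ne_b = 8e4, ne_anc = 1.5e5, t = 3e5)
  obs <- tibble::tibble(partition = "inv_x", dxy = 0.003, fst = 0.5,
                        n_blocks = 200)
  expect_error(inversion_null_test(pars, obs, n_sims = 10), "at least 20")

  nt <- inversion_null_test(pars, obs, model = "div", n_sims = 25,
                            seq_length = 2e4, seed = 8)
  res <- tidy(nt)
  expect_equal(nrow(res), 1)
  expect_gt(res$p_dxy, 0)
  expect_lte(res$p_dxy, 1)
  expect_equal(nrow(nt$results$null[[1]]), 25)
  # observed far above anything the background can produce
  obs_hi <- tibble::tibble(partition = "inv_hi", dxy = 0.5, fst = 0.99,
                           n_blocks = 200)
  nt_hi <- inversion_null_test(pars, obs_hi, model = "div", n_sims = 25,
                               seq_length = 2e4, seed = 8)
  expect_equal(nt_hi$spec$model, "div")
  expect_equal(tidy(nt_hi)$p_dxy, 1 / 26)
})

test_that("more gene conversion reduces between-replicate variance of mean d_xy", {
  # with more initiation events a sequence averages over more genealogies,
  # so replicate means concentrate (checked over a 3-point rate grid)
  bg <- list(ne_a = 1e5, ne_b = 1e5, ne_anc = 1e5, t = 4e5)
  obs <- tibble::tibble(partition = "v", dxy = 0.01, n_blocks = 700)
  vars <- purrr::map_dbl(c(3.59e-9, 3.59e-8, 3.59e-7), function(g) {
    nt <- inversion_null_test(bg, obs, model = "div", n_sims = 120,
                              seq_length = 5e4, gc_rate = g, seed = 21)
    stats::var(nt$results$null[[1]]$dxy)
  })
  expect_true(all(diff(vars) < 0))
})
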