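# the matrix-exponential probability engine against analytic limits and the
# independent Monte-Carlo genealogy simulator (mc_config_freqs in helpers)

test_that("probability tables normalize and vanish correctly in limits", {
  pars <- pars_sympatric_im()
  for (model in c("div", "im_ab", "im_ba")) {
    pp <- if (model == "div") pars[1:4] else pars
    pr <- bsfs_probs(model, pp)
    expect_lt(abs(sum(pr$prob) - 1), 1e-8)
    expect_true(all(pr$prob >= -1e-12))
  }
  # theta -> 0: all mass on the zero configuration
  pr0 <- bsfs_probs("div", pars[1:4], mu = 1e-15)
  expect_gt(pr0$prob[pr0$hetA == 0 & pr0$hetB == 0 & pr0$hetAB == 0 &
                       pr0$fixed == 0], 1 - 1e-4)
  expect_error(bsfs_probs("div", list(ne_a = 1, ne_b = 1, ne_anc = Inf,
                                      t = 1)), "finite")
})

test_that("expected fixed differences are non-decreasing in split time at m = 0", {
  ts <- c(1e5, 5e5, 1e6, 3e6, 6e6)
  efix <- purrr::map_dbl(ts, function(t) {
    pr <- bsfs_probs("div", list(ne_a = 5e5, ne_b = 5e5, ne_anc = 5e5,
                                 t = t))
    sum(pr$prob * pr$fixed) # truncated mean is enough for monotonicity
  })
  expect_true(all(diff(efix) > 0))
})

test_that("swapping population labels and migration direction leaves the model invariant", {
  pars <- pars_sympatric_im()
  pr_ab <- bsfs_probs("im_ab", pars)
  swapped <- list(ne_a = pars$ne_b, ne_b = pars$ne_a, ne_anc = pars$ne_anc,
                  t = pars$t, m = pars$m)
  pr_ba <- bsfs_probs("im_ba", swapped)
  # relabelling A<->B swaps the hetA and hetB axes
  key_sw <- with(pr_ba, paste(hetB, hetA, hetAB, fixed))
  key <- with(pr_ab, paste(hetA, hetB, hetAB, fixed))
  expect_equal(pr_ab$prob, pr_ba$prob[match(key, key_sw)], tolerance = 1e-10)
})

test_that("composite log-likelihood is linear and matches single configurations", {
  pars <- pars_sympatric_im()
  pr <- bsfs_probs("im_ab", pars)
  one <- pr[which.max(pr$prob), c("hetA", "hetB", "hetAB", "fixed")]
  one$n <- 1
  attr(one, "kmax") <- 2
  expect_equal(composite_loglik(one, pr), log(max(pr$prob)))
  two <- one
  two$n <- 2
  attr(two, "kmax") <- 2
  expect_equal(composite_loglik(two, pr), 2 * composite_loglik(one, pr))
})

test_that("the expected lnCL is maximized at the generating parameters", {
  # a tally of exact expected counts: any parameter perturbation lowers lnCL
  pars <- pars_sympatric_im()
  pr <- bsfs_probs("im_ab", pars)
  tal <- pr
  names(tal)[names(tal) == "prob"] <- "n"
  tal$n <- tal$n * 1e5
  attr(tal, "kmax") <- 2
  base <- composite_loglik(tal, pr)
  for (fac in c(0.8, 1.25)) {
    for (term in c("t", "ne_anc", "m")) {
      pp <- pars
      pp[[term]] <- pp[[term]] * fac
      expect_lt(composite_loglik(tal, bsfs_probs("im_ab", pp)), base)
    }
  }
})

test_that("analytic probabilities match the Monte-Carlo genealogy oracle", {
  # a modest grid here; the full 12-point grid runs in the acceptance suite
  grid <- list(
    list(model = "div", pars = pars_intraspecific_div()),
    list(model = "im_ab", pars = pars_sympatric_im()),
    list(model = "im_ba", pars = list(ne_a = 3e5, ne_b = 9e5, ne_anc = 5e5,
                                      t = 4e6, m = 5e-8)))
  set.seed(99)
  n <- 3e5
  for (g in grid) {
    pr <- bsfs_probs(g$model, g$pars)
    emp <- mc_config_freqs(g$model, g$pars, n)
    sel <- pr$prob > 1e-3
    z <- (emp[sel] - pr$prob[sel]) /
      sqrt(pr$prob[sel] * (1 - pr$prob[sel]) / n)
    expect_lt(max(abs(z)), 4.5) # familywise bound over ~50 configurations
    expect_gt(mean(abs(z) < 3), 0.9)
  }
})
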