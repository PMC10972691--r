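# fast internal likelihood path used by the optimizer (index arithmetic
# instead of tibble joins)
.prob_vec <- function(model, p, sp, block_length, mu) {
  nref <- p$ne_anc
  theta_half <- 2 * nref * mu * block_length
  base1 <- c(nref / p$ne_a, nref / p$ne_b,
             if (model == "im_ab") 2 * nref * p$m else 0,
             if (model == "im_ba") 2 * nref * p$m else 0,
             theta_half)
  base2 <- c(1, theta_half)
  bsfs_engine_cpp(sp$n1full, sp$e1_from, sp$e1_to, sp$e1_type, sp$e1_mult,
                  base1, p$t / (2 * nref), sp$p0, sp$proj, sp$n2full,
                  sp$e2_from, sp$e2_to, sp$e2_type, sp$e2_mult, base2,
                  sp$e2_ptr, sp$topo, sp$absorb, sp$nc)
}

.tally_index <- function(tally, K) {
  1L + tally$hetA + tally$hetB * K + tally$hetAB * K^2L + tally$fixed * K^3L
}

default_bounds <- function() {
  list(ne = c(1e4, 5e7), t = c(1e3, 1e8), m = c(1e-13, 1e-6))
}

.param_bounds <- function(free, bounds) {
  lo <- hi <- numeric(length(free))
  for (i in seq_along(free)) {
    b <- switch(free[i], ne_a = , ne_b = , ne_anc = bounds$ne,
                t = bounds$t, m = bounds$m)
    lo[i] <- b[1]; hi[i] <- b[2]
  }
  list(lo = lo, hi = hi)
}

# moment-based starting point: within-species diversity sets the daughter
# sizes, mean divergence sets split time given an ancestral-size guess
.moment_start <- function(tally, block_length, mu) {
  n <- sum(tally$n)
  mc <- vapply(mutation_types, function(tp) sum(tally[[tp]] * tally$n) / n,
               numeric(1))
  pi_a <- (mc[["hetA"]] + mc[["hetAB"]]) / block_length
  pi_b <- (mc[["hetB"]] + mc[["hetAB"]]) / block_length
  dxy <- (0.5 * (mc[["hetA"]] + mc[["hetB"]] + mc[["hetAB"]]) + mc[["fixed"]]) /
    block_length
  ne_a <- max(pi_a / (4 * mu), 2e4)
  ne_b <- max(pi_b / (4 * mu), 2e4)
  ne_anc <- (ne_a + ne_b) / 2
  t0 <- max(dxy / (2 * mu) - 2 * ne_anc, 5e3)
  list(ne_a = ne_a, ne_b = ne_b, ne_anc = ne_anc, t = t0, m = 1e-9)
}

#' Fit a DIV or IM model to a bSFS tally by composite likelihood
#'
#' Maximizes the composite log-likelihood `lnCL` over the free demographic
#' parameters with a multi-start Nelder-Mead search on log-scaled parameters.
#' The DIV model has four free parameters (`ne_a`, `ne_b`, `ne_anc`, `t`);
#' the IM models add the migration probability `m`.
#'
#' @inheritParams bsfs_probs
#' @param tally A bSFS tally (tibble with `hetA`, `hetB`, `hetAB`, `fixed`,
#'   `n`; `kmax` and `block_length` attributes as produced by [tally_bsfs()]
#'   or [sim_tally()]).
#' @param n_starts Number of optimizer starts.  The first start is the
#'   moment-based heuristic (or `init` if supplied); the rest are drawn
#'   log-uniform within `bounds`.
#' @param seed Integer seed controlling the random starts.
#' @param free Character vector of parameters to optimize; the rest are held
#'   at `init` (defaults to all parameters of the model).
#' @param init Optional named list of starting/fixed parameter values.
#' @param bounds List with elements `ne`, `t`, `m`, each `c(lower, upper)`.
#' @param kmax,block_length Defaults are taken from the tally attributes.
#' @param control Passed to [stats::optim()] (Nelder-Mead); the default stops
#'   at a relative lnCL tolerance of about 1e-4.
#' @return An object of class `bsfs_fit` with parameter estimates (absolute
#'   and scaled), `lnCL`, a convergence flag and the per-start trace.
#'   Supports [tidy()], [glance()] and `print()`.
#' @seealso [compare_fits()], [parametric_bootstrap()]
#' @export
fit_bsfs <- function(tally, model, mu = 2.8e-9, n_starts = 5, seed = 1,
                     free = NULL, init = NULL, bounds = default_bounds(),
                     kmax = attr(tally, "kmax"),
                     block_length = attr(tally, "block_length"),
                     control = list()) {
  model <- match.arg(model, c("div", "im_ab", "im_ba"))
  if (is.null(kmax) || is.null(block_length)) {
    stop("tally lacks kmax/block_length attributes; pass them explicitly",
         call. = FALSE)
  }
  if (!nrow(tally) || sum(tally$n) <= 0) stop("empty tally", call. = FALSE)
  control <- utils::modifyList(list(maxit = 1500, reltol = 1e-10), control)
  sp <- .engine_space(kmax, switch(model, div = "div", im_ab = "ab",
                                   im_ba = "ba"))
  idx <- .tally_index(tally, sp$K)
  nn <- tally$n

  all_pars <- c("ne_a", "ne_b", "ne_anc", "t", if (model != "div") "m")
  free <- free %||% all_pars
  if (!all(free %in% all_pars)) {
    stop("`free` must be a subset of: ", paste(all_pars, collapse = ", "),
         call. = FALSE)
  }
  start0 <- utils::modifyList(.moment_start(tally, block_length, mu),
                              as.list(init %||% list()))
  if (model == "div") start0$m <- 0
  pb <- .param_bounds(free, bounds)

  assemble <- function(x) {
    p <- start0
    p[free] <- as.list(10^x)
    p
  }
  negll <- function(x) {
    if (any(!is.finite(x)) || any(10^x < pb$lo) || any(10^x > pb$hi)) {
      return(1e12)
    }
    p <- assemble(x)
    Tsc <- p$t / (2 * p$ne_anc)
    lam <- 6 * p$ne_anc / min(p$ne_a, p$ne_b) +
      4 * p$ne_anc * mu * block_length + 4 * p$ne_anc * (p$m %||% 0)
    if (Tsc > 30 || lam * Tsc > 2e4) return(1e10 * (1 + log1p(Tsc)))
    pr <- .prob_vec(model, p, sp, block_length, mu)
    pv <- pr[idx]
    if (any(pv <= 0 & nn > 0)) return(1e12)
    -sum(nn * log(pv))
  }

  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  starts <- list(log10(clamp(unlist(start0[free]), pb$lo, pb$hi)))
  if (n_starts > 1) {
    seeds <- spawn_seeds(seed, n_starts - 1L)
    for (s in seq_len(n_starts - 1L)) {
      starts[[s + 1L]] <- with_seed_if(seeds[s], {
        for (try in 1:200) {
          x <- runif(length(free), log10(pb$lo), log10(pb$hi))
          p <- assemble(x)
          if (p$t / (2 * p$ne_anc) <= 20) break
        }
        x
      })
    }
  }

  runs <- purrr::map(starts, function(x0) {
    tryCatch({
      if (length(free) == 1L) {
        optim(x0, negll, method = "Brent", lower = log10(pb$lo),
              upper = log10(pb$hi),
              control = control[setdiff(names(control), "reltol")])
      } else {
        optim(x0, negll, method = "Nelder-Mead", control = control)
      }
    }, error = function(e) list(value = Inf, par = x0, convergence = 99L,
                                message = conditionMessage(e)))
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals))) stop("all optimizer starts failed", call. = FALSE)
  best <- runs[[which.min(vals)]]
  est <- assemble(best$par)

  recipient <- switch(model, im_ab = "ne_b", im_ba = "ne_a", NA_character_)
  Mhat <- if (model == "div") NA_real_ else M_from_m(est$m, est[[recipient]])
  params <- tibble::tibble(
    term = c("ne_a", "ne_b", "ne_anc", "t", "m", "M", "T_anc"),
    estimate = c(est$ne_a, est$ne_b, est$ne_anc, est$t,
                 if (model == "div") 0 else est$m, Mhat,
                 T_from_t(est$t, est$ne_anc)))
  trace <- tibble::tibble(
    start = seq_along(runs),
    lnCL = -vals,
    convergence = vapply(runs, function(r) as.integer(r$convergence %||% 99L),
                         integer(1)))
  structure(list(model = model, params = params, estimate = est,
                 lnCL = -best$value,
                 converged = identical(best$convergence, 0L),
                 trace = trace, n_blocks = sum(nn), kmax = kmax,
                 block_length = block_length, mu = mu, free = free),
            class = "bsfs_fit")
}

#' @export
print.bsfs_fit <- function(x, ...) {
  cat(sprintf("bSFS composite-likelihood fit (%s model)\n", toupper(x$model)))
  cat(sprintf("  blocks: %d (length %d, kmax %d)   lnCL: %.2f   converged: %s\n",
              x$n_blocks, x$block_length, x$kmax, x$lnCL, x$converged))
  e <- x$estimate
  cat(sprintf("  Ne_A = %.3g  Ne_B = %.3g  Ne_anc = %.3g  t = %.3g gen  m = %.3g\n",
              e$ne_a, e$ne_b, e$ne_anc, e$t, e$m %||% 0))
  invisible(x)
}

#' @rdname fit_bsfs
#' @param x A `bsfs_fit` object.
#' @param ... Unused.
#' @export
tidy.bsfs_fit <- function(x, ...) x$params

#' @rdname fit_bsfs
#' @export
glance.bsfs_fit <- function(x, ...) {
  tibble::tibble(model = x$model, lnCL = x$lnCL, n_blocks = x$n_blocks,
                 kmax = x$kmax, block_length = x$block_length,
                 converged = x$converged)
}

#' Compare two model fits on the same tally
#'
#' Reports the composite log-likelihood difference `delta lnCL` between an
#' alternative and a null fit.  Significance should come from
#' [parametric_bootstrap()], not from chi-square asymptotics, because blocks
#' are not independent draws from the composite likelihood.
#'
#' @param fit_alt,fit_null `bsfs_fit` objects fitted to the same tally.
#' @return One-row tibble with both lnCL values, `delta_lnCL`
#'   (`lnCL_alt - lnCL_null`) and the better-supported model.
#' @export
compare_fits <- function(fit_alt, fit_null) {
  if (fit_alt$n_blocks != fit_null$n_blocks ||
      fit_alt$kmax != fit_null$kmax ||
      fit_alt$block_length != fit_null$block_length) {
    stop("fits are not based on the same tally", call. = FALSE)
  }
  d <- fit_alt$lnCL - fit_null$lnCL
  tibble::tibble(model_alt = fit_alt$model, model_null = fit_null$model,
                 lnCL_alt = fit_alt$lnCL, lnCL_null = fit_null$lnCL,
                 delta_lnCL = d,
                 best = if (d >= 0) fit_alt$model else fit_null$model)
}
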