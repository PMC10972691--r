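#' Gene-conversion-only simulation null for inversion divergence
#'
#' Tests whether observed `d_xy` (and `F_ST`) inside an inversion exceeds
#' what the colinear background demography can produce.  Replicate datasets
#' are simulated under the background history with a minimal, conservative
#' model of recombination inside inversions: gene conversion (geometric
#' tract lengths) but no crossover.  Each replicate simulates sequences of
#' `seq_length` bp, cut into blocks and matched in block count to the data
#' observed for the inversion; one-sided p-values use the add-one
#' estimator.
#'
#' @param background Background demographic parameters: a `bsfs_fit` (from
#'   the colinear autosomal fit) or a named list with `ne_a`, `ne_b`,
#'   `ne_anc`, `t` and optionally `m`.
#' @param observed Tibble with one row per inversion partition: `partition`,
#'   `dxy`, `fst`, `n_blocks` (e.g. from [partition_stats()]).
#' @param model Demographic model for the null (default `"im_ab"`; `"div"`
#'   if the background has no migration).
#' @param n_sims Number of null replicates (>= 20; default 1000 so that
#'   p < 0.001 is resolvable).
#' @param seq_length Simulated sequence length in bp (default 100 kb).
#' @param gc_rate Gene-conversion initiation rate per bp per generation
#'   (default 3.59e-8; see [gc_initiation_rate()]).
#' @param gc_tract Mean gene-conversion tract length in bp (default 390).
#' @param block_length Sites per block (default 64).
#' @param mu Mutation rate per site per generation.
#' @param alternative `"greater"` (elevated divergence inside inversions is
#'   the hypothesis) or `"two.sided"`.
#' @param seed Master seed.
#' @return An object of class `inv_null`: tibble `results` with per-
#'   partition observed values, null means and p-values, plus the null
#'   distributions in a list-column `null`.
#' @export
inversion_null_test <- function(background, observed, model = "im_ab",
                                n_sims = 1000, seq_length = 1e5,
                                gc_rate = 3.59e-8, gc_tract = 390,
                                block_length = 64, mu = 2.8e-9,
                                alternative = c("greater", "two.sided"),
                                seed = 1) {
  alternative <- match.arg(alternative)
  if (n_sims < 20) {
    stop("n_sims must be at least 20 for any p-value resolution",
         call. = FALSE)
  }
  pars <- if (inherits(background, "bsfs_fit")) {
    background$estimate
  } else as.list(background)
  model <- if ((pars$m %||% 0) <= 0) "div" else match.arg(model, c("im_ab", "im_ba"))
  stopifnot(all(c("partition", "dxy", "n_blocks") %in% names(observed)))
  seeds <- spawn_seeds(seed, nrow(observed))

  rows <- purrr::map(seq_len(nrow(observed)), function(i) {
    nb <- observed$n_blocks[i]
    cfg <- list(mode = "gcnull", demography = demography_cfg(model, pars),
                mu = mu, block_length = as.integer(block_length),
                seq_length = seq_length, gc_rate = gc_rate,
                gc_tract = gc_tract, n_blocks = as.integer(nb),
                n_sims = as.integer(n_sims), seed = seeds[i])
    sims <- run_msprime(cfg)
    null <- tibble::tibble(
      dxy = (0.5 * (sims$hetA + sims$hetB + sims$hetAB) + sims$fixed) /
        (sims$n_blocks * block_length),
      pi_a = (sims$hetA + sims$hetAB) / (sims$n_blocks * block_length),
      pi_b = (sims$hetB + sims$hetAB) / (sims$n_blocks * block_length))
    null$fst <- ifelse(null$dxy > 0,
                       1 - ((null$pi_a + null$pi_b) / 2) / null$dxy,
                       NA_real_)
    pval <- function(obs, vec) {
      up <- (1 + sum(vec >= obs, na.rm = TRUE)) / (sum(!is.na(vec)) + 1)
      if (alternative == "greater") return(up)
      dn <- (1 + sum(vec <= obs, na.rm = TRUE)) / (sum(!is.na(vec)) + 1)
      min(1, 2 * min(up, dn))
    }
    has_fst <- "fst" %in% names(observed)
    tibble::tibble(partition = observed$partition[i],
                   n_blocks = nb,
                   dxy_obs = observed$dxy[i],
                   dxy_null_mean = mean(null$dxy),
                   p_dxy = pval(observed$dxy[i], null$dxy),
                   fst_obs = if (has_fst) observed$fst[i] else NA_real_,
                   fst_null_mean = mean(null$fst, na.rm = TRUE),
                   p_fst = if (has_fst) pval(observed$fst[i], null$fst)
                   else NA_real_,
                   null = list(null))
  })
  structure(list(results = dplyr::bind_rows(rows),
                 spec = list(model = model, n_sims = n_sims,
                             seq_length = seq_length, gc_rate = gc_rate,
                             gc_tract = gc_tract,
                             block_length = block_length, mu = mu,
                             alternative = alternative, seed = seed,
                             params = pars)),
            class = "inv_null")
}

#' @export
print.inv_null <- function(x, ...) {
  cat(sprintf("Inversion null test (gene conversion only, %d sims)\n",
              x$spec$n_sims))
  print(dplyr::select(x$results, -"null"))
  invisible(x)
}

#' @rdname inversion_null_test
#' @param x An `inv_null` object.
#' @param ... Unused.
#' @export
tidy.inv_null <- function(x, ...) dplyr::select(x$results, -"null")
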