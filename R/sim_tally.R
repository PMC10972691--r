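#' Simulate a bSFS tally under a DIV or IM model
#'
#' Draws blockwise mutation configurations for one heterospecific pair of
#' diploids under the given demographic history.  By default blocks are
#' unlinked (`n_chunks = n_blocks`): each block gets an independent
#' four-lineage genealogy from the native structured-coalescent simulator and
#' Poisson mutation counts per branch-type class.  With `n_chunks < n_blocks`
#' blocks are linked within chunks: at `r = 0` all blocks of a chunk share
#' one genealogy (full linkage); at `r > 0` each chunk is simulated as a
#' recombining sequence with msprime and cut into blocks, the configuration
#' used for parametric-bootstrap realism.
#'
#' @inheritParams bsfs_probs
#' @param n_blocks Total number of blocks.
#' @param n_chunks Number of independently segregating chunks
#'   (`1 <= n_chunks <= n_blocks`); blocks are distributed evenly.
#' @param r Recombination rate per bp per generation between sites within a
#'   chunk (default 0).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tally tibble (`hetA`, `hetB`, `hetAB`, `fixed`, `n`) with
#'   `kmax` and `block_length` attributes, exchangeable with empirical
#'   tallies from [tally_bsfs()].
#' @examples
#' pars <- list(ne_a = 7.4e5, ne_b = 3.8e5, ne_anc = 1.4e6, t = 2.5e6,
#'              m = 1.3e-8)
#' tal <- sim_tally("im_ab", pars, n_blocks = 1000, seed = 1)
#' sum(tal$n)
#' @export
sim_tally <- function(model, params, n_blocks, block_length = 64, kmax = 2,
                      mu = 2.8e-9, n_chunks = n_blocks, r = 0, seed = NULL) {
  model <- match.arg(model, c("div", "im_ab", "im_ba"))
  p <- validate_params(params, model)
  stopifnot(n_blocks >= 1, n_chunks >= 1, n_chunks <= n_blocks, r >= 0)
  base <- n_blocks %/% n_chunks
  bpc <- rep.int(base, n_chunks)
  extra <- n_blocks - base * n_chunks
  if (extra > 0) bpc[seq_len(extra)] <- bpc[seq_len(extra)] + 1L

  if (r == 0 || n_chunks == n_blocks) {
    counts <- with_seed_if(seed, {
      nref <- p$ne_anc
      L <- sim_pair_lengths_cpp(
        as.integer(n_chunks), nref / p$ne_a, nref / p$ne_b,
        if (model == "im_ab") 2 * nref * p$m else 0,
        if (model == "im_ba") 2 * nref * p$m else 0,
        p$t / (2 * nref), 1)
      theta_half <- 2 * nref * mu * block_length
      Lb <- L[rep.int(seq_len(n_chunks), bpc), , drop = FALSE]
      matrix(rpois(length(Lb), theta_half * Lb), ncol = 4L)
    })
  } else {
    cfg <- list(mode = "chunks",
                demography = demography_cfg(model, p),
                mu = mu, block_length = as.integer(block_length),
                r = r, blocks_per_chunk = as.integer(bpc),
                seed = as.integer(seed %||% sample.int(2^31 - 2, 1)))
    res <- run_msprime(cfg)
    counts <- as.matrix(res[, mutation_types])
  }
  new_tally(truncate_counts(counts, kmax), kmax, block_length)
}
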