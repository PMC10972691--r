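# Shared fixtures and independent oracles used across test files.

# Table-style parameter sets used throughout (interspecific sympatric IM and
# intraspecific DIV histories)
pars_sympatric_im <- function() {
  list(ne_a = 735000, ne_b = 377000, ne_anc = 1388000, t = 2526000,
       m = 1.29e-8)
}
pars_intraspecific_div <- function() {
  list(ne_a = 1087000, ne_b = 1560000, ne_anc = 858000, t = 210000)
}

# closed-form expectations under strict divergence (independent oracle):
# within-species pair coalescence switches from the daughter to the
# ancestral population at t; cross-species pairs cannot coalesce before t
ET_within <- function(ne, ne_anc, t) {
  2 * ne * (1 - exp(-t / (2 * ne))) + exp(-t / (2 * ne)) * 2 * ne_anc
}
ET_cross <- function(ne_anc, t) t + 2 * ne_anc

# small five-inversion scenario scaled to short chromosomes
small_inversions <- function(len = 60000) {
  tibble::tibble(chrom = c("4", "5", "X", "X", "X"),
                 start = round(len * c(1 / 3, 1 / 3, 1 / 6, 5 / 12, 2 / 3)),
                 end = round(len * c(3 / 4, 2 / 3, 1 / 2, 3 / 4, 5 / 6)),
                 carrier = c("B", "B", "A", "B", "B"))
}
small_scenario <- function(len = 60000, n_a = 3, n_b = 3, seed = 1, ...) {
  sim_scenario(chromosomes = default_chromosomes(len),
               inversions = small_inversions(len), n_a = n_a, n_b = n_b,
               seed = seed, ...)
}

# per-site brute-force classification of a pair of dosage vectors, used as
# the oracle for blockwise counting
brute_force_counts <- function(dos_a, dos_b) {
  c(hetA = sum(dos_a == 1 & dos_b != 1, na.rm = TRUE),
    hetB = sum(dos_b == 1 & dos_a != 1, na.rm = TRUE),
    hetAB = sum(dos_a == 1 & dos_b == 1, na.rm = TRUE),
    fixed = sum(abs(dos_a - dos_b) == 2, na.rm = TRUE))
}

# brute-force per-base interval set difference on small ranges
brute_force_setdiff <- function(x, y, max_bp = 10000) {
  keep <- rep(FALSE, max_bp)
  for (i in seq_len(nrow(x))) keep[(x$start[i] + 1):x$end[i]] <- TRUE
  for (i in seq_len(nrow(y))) keep[(y$start[i] + 1):y$end[i]] <- FALSE
  which(keep) - 1 # 0-based positions retained
}

# positions covered by an interval tibble (0-based)
iv_positions <- function(x) {
  unlist(purrr::map2(x$start, x$end, function(s, e) seq(s, e - 1)))
}

# empirical configuration frequencies from the Monte-Carlo genealogy
# simulator (independent of the matrix-exponential engine)
mc_config_freqs <- function(model, pars, n, kmax = 2, l = 64, mu = 2.8e-9) {
  nref <- pars$ne_anc
  L <- invdemog:::sim_pair_lengths_cpp(
    n, nref / pars$ne_a, nref / pars$ne_b,
    if (model == "im_ab") 2 * nref * pars$m else 0,
    if (model == "im_ba") 2 * nref * pars$m else 0,
    pars$t / (2 * nref), 1)
  th <- 2 * nref * mu * l
  cnt <- pmin(matrix(rpois(length(L), th * L), ncol = 4), kmax + 1)
  K <- kmax + 2
  idx <- 1 + cnt[, 1] + cnt[, 2] * K + cnt[, 3] * K^2 + cnt[, 4] * K^3
  tabulate(idx, K^4) / n
}
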