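#' Divergence and diversity per genomic partition
#'
#' From per-block mutation-type counts, computes for each partition the mean
#' per-site divergence `d_xy`, within-species diversities `pi_A`, `pi_B`
#' and Hudson's `F_ST = 1 - mean(pi_A, pi_B) / d_xy` on block-aggregated
#' quantities.  Per block and pair, `d_xy = (hetA/2 + hetB/2 + hetAB/2 +
#' fixed) / block_length` (the average over the four heterospecific
#' haplotype pairs), `pi_A = (hetA + hetAB) / block_length` (the A
#' individual is heterozygous at hetAB sites too) and symmetrically for
#' `pi_B`.
#'
#' @param counts Output of [block_counts()] (needs at least the four count
#'   columns and `partition`).
#' @param block_length Sites per block; defaults to the attribute on
#'   `counts`.
#' @return Tibble with one row per partition: `partition`, `n_blocks`
#'   (pair-block observations), `dxy`, `pi_a`, `pi_b`, `fst` (`NA` where
#'   `dxy = 0`).
#' @export
partition_stats <- function(counts, block_length = attr(counts, "block_length")) {
  if (is.null(block_length)) stop("block_length unknown", call. = FALSE)
  if (!nrow(counts)) stop("no blocks", call. = FALSE)
  grp <- if ("partition" %in% names(counts)) "partition" else NULL
  df <- dplyr::mutate(counts,
                      .dxy = (0.5 * (.data$hetA + .data$hetB + .data$hetAB) +
                                .data$fixed) / block_length,
                      .pa = (.data$hetA + .data$hetAB) / block_length,
                      .pb = (.data$hetB + .data$hetAB) / block_length)
  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
    n_blocks = dplyr::n(),
    dxy = mean(.data$.dxy), pi_a = mean(.data$.pa), pi_b = mean(.data$.pb),
    .groups = "drop")
  out$fst <- ifelse(out$dxy > 0,
                    1 - ((out$pi_a + out$pi_b) / 2) / out$dxy, NA_real_)
  out
}

#' Sliding-window divergence scan
#'
#' Orders blocks along each chromosome, averages `d_xy` over all pairs per
#' block, and slides a window of `window` blocks advanced by `step` blocks.
#' Windows never span chromosome boundaries; trailing windows with fewer
#' than `window` blocks are dropped.
#'
#' @inheritParams partition_stats
#' @param window Window size in blocks (default 5000).
#' @param step Step size in blocks (default 500).
#' @return A tibble of class `dxy_scan` with `chrom`, `start`, `end`, `mid`
#'   (bp) and `dxy` per window.
#' @export
sliding_window_dxy <- function(counts, window = 5000, step = 500,
                               block_length = attr(counts, "block_length")) {
  stopifnot(window >= step, step >= 1)
  if (is.null(block_length)) stop("block_length unknown", call. = FALSE)
  per_block <- dplyr::summarise(
    dplyr::group_by(counts, .data$chrom, .data$start, .data$end),
    dxy = mean((0.5 * (.data$hetA + .data$hetB + .data$hetAB) +
                  .data$fixed) / block_length),
    .groups = "drop")
  per_block <- dplyr::arrange(per_block, .data$chrom, .data$start)
  out <- purrr::map_dfr(unique(per_block$chrom), function(ch) {
    d <- per_block[per_block$chrom == ch, ]
    nb <- nrow(d)
    if (nb < window) return(tibble::tibble())
    first <- seq(1L, nb - window + 1L, by = step)
    cs <- c(0, cumsum(d$dxy))
    tibble::tibble(chrom = ch,
                   start = d$start[first],
                   end = d$end[first + window - 1L],
                   mid = (d$start[first] + d$end[first + window - 1L]) / 2,
                   dxy = (cs[first + window] - cs[first]) / window)
  })
  class(out) <- c("dxy_scan", class(out))
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' G-test of independence for a 2x2 table
#'
#' Likelihood-ratio (G) test, `G = 2 * sum(O * ln(O / E))` with expected
#' counts from the independence model and the p-value from the upper tail
#' of a chi-square distribution with one degree of freedom.  Used to test
#' whether positively selected genes are enriched inside inversions.  No
#' continuity or Williams correction is applied.
#'
#' @param x A 2x2 matrix of non-negative counts, or a length-4 vector
#'   (filled by row: a, b, c, d).
#' @return Tibble with `statistic` (G), `df` and `p_value`.
#' @examples
#' gtest_2x2(c(45, 1952, 112, 5314))
#' @export
gtest_2x2 <- function(x) {
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), 2, 2, byrow = TRUE)
  if (!all(dim(m) == 2) || any(m < 0) || any(!is.finite(m))) {
    stop("x must be a 2x2 table of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all marginals must be positive", call. = FALSE)
  }
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  terms <- ifelse(m > 0, m * log(m / e), 0)
  g <- 2 * sum(terms)
  tibble::tibble(statistic = g, df = 1L,
                 p_value = pchisq(g, df = 1, lower.tail = FALSE))
}
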