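#' Simulate caller-style structural-variant inversion tables
#'
#' Produces two noisy per-caller tables of inversion calls from the truth
#' scenario, emulating the output of read-based SV callers: every true fixed
#' inversion is reported for each sample of the carrier species by each
#' caller unless dropped at the false-negative rate; breakpoints are
#' jittered with Gaussian noise per call; false positives are random small
#' intervals attributed to random samples.
#'
#' @param scenario An `inv_scenario`.
#' @param jitter_sd Breakpoint jitter standard deviation in bp.
#' @param fn_rate Per-sample per-caller probability that a true call is
#'   missed (in `[0, 1]`).
#' @param fp_rate Per-sample per-caller expected number of false-positive
#'   calls (in `[0, 1]`).
#' @param seed Integer seed (default: scenario seed + 2).
#' @return A list of two tibbles (`caller1`, `caller2`) with columns
#'   `chrom`, `start`, `end`, `type`, `sample`, `species`, `caller`.
#' @examples
#' sc <- sim_scenario(seed = 3)
#' calls <- sim_sv_calls(sc, jitter_sd = 0, fn_rate = 0, fp_rate = 0)
#' nrow(calls$caller1)
#' @export
sim_sv_calls <- function(scenario, jitter_sd = 150, fn_rate = 0.05,
                         fp_rate = 0.02, seed = scenario$seed + 2L) {
  stopifnot(inherits(scenario, "inv_scenario"))
  if (fn_rate < 0 || fn_rate > 1 || fp_rate < 0 || fp_rate > 1 ||
      jitter_sd < 0) {
    stop("noise rates must lie in [0, 1] and jitter_sd must be >= 0",
         call. = FALSE)
  }
  inv <- scenario$inversions
  smp <- scenario$samples
  lens <- setNames(scenario$chromosomes$length, scenario$chromosomes$chrom)

  empty_calls <- tibble::tibble(chrom = character(), start = numeric(),
                                end = numeric(), type = character(),
                                sample = character(), species = character(),
                                caller = character())
  with_seed_if(seed, {
    out <- purrr::map(c("caller1", "caller2"), function(cl) {
      true_calls <- if (nrow(inv)) {
        purrr::map_dfr(seq_len(nrow(inv)), function(i) {
          carriers <- smp$sample[smp$species == inv$carrier[i]]
          keep <- runif(length(carriers)) >= fn_rate
          carriers <- carriers[keep]
          if (!length(carriers)) return(empty_calls)
          n <- length(carriers)
          s <- round(inv$start[i] + stats::rnorm(n, 0, jitter_sd))
          e <- round(inv$end[i] + stats::rnorm(n, 0, jitter_sd))
          s <- pmax(s, 0)
          e <- pmin(pmax(e, s + 1), lens[inv$chrom[i]])
          tibble::tibble(chrom = inv$chrom[i], start = s, end = e,
                         type = "INV", sample = carriers,
                         species = inv$carrier[i], caller = cl)
        })
      } else empty_calls
      n_fp <- rpois(1, fp_rate * nrow(smp))
      fp <- if (n_fp > 0) {
        ch <- sample(names(lens), n_fp, replace = TRUE)
        w <- round(stats::rlnorm(n_fp, log(5e4), 0.5))
        s <- floor(runif(n_fp, 0, pmax(lens[ch] - w, 1)))
        who <- sample(smp$sample, n_fp, replace = TRUE)
        tibble::tibble(chrom = ch, start = s, end = pmin(s + w, lens[ch]),
                       type = "INV", sample = who,
                       species = smp$species[match(who, smp$sample)],
                       caller = cl)
      } else empty_calls
      dplyr::arrange(dplyr::bind_rows(true_calls, fp),
                     .data$chrom, .data$start, .data$sample)
    })
    names(out) <- c("caller1", "caller2")
    out
  })
}
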