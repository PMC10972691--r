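# Default study-like truth scenario: two species (A, montana-like, 12
# samples; B, flavomontana-like, 9 samples), five fixed inversions (one on
# each of chromosomes 4 and 5, three overlapping on the X), partition-wise
# IM histories in which inversions are older and exchange fewer migrants
# than the colinear background.  Chromosome lengths are kept short so that
# whole datasets can be simulated quickly; they are configuration, not
# biology.

#' Default scenario building blocks
#'
#' Study-like defaults used by [sim_scenario()]: five chromosomes (four
#' autosomes and an X), five alternatively fixed inversions (three
#' overlapping on the X) and partition-wise demographic parameters under
#' which the inversions predate the colinear split time and receive less
#' migration.
#'
#' @param length Chromosome length in bp.
#' @return A tibble (see [sim_scenario()] for the expected columns).
#' @export
default_chromosomes <- function(length = 250000) {
  tibble::tibble(chrom = c("2", "3", "4", "5", "X"),
                 length = length,
                 class = c(rep("autosome", 4), "X"))
}

#' @rdname default_chromosomes
#' @export
default_inversions <- function() {
  tibble::tibble(
    chrom = c("4", "5", "X", "X", "X"),
    start = c(80000, 80000, 40000, 100000, 160000),
    end = c(200000, 180000, 140000, 180000, 220000),
    carrier = c("B", "B", "A", "B", "B"))
}

# partition-wise demographic parameters: colinear background with recent-er
# split and more migration; inversions older with less migration
#' @rdname default_chromosomes
#' @export
default_partition_params <- function() {
  tibble::tribble(
    ~partition, ~ne_a, ~ne_b, ~ne_anc, ~t, ~m,
    "auto_col", 735000, 377000, 1388000, 2526000, 1.29e-8,
    "inv_4", 865000, 470000, 1603000, 2988000, 0.0067 / (2 * 470000),
    "inv_5", 752000, 392000, 1321000, 2823000, 0.0076 / (2 * 392000),
    "x_col", 493000, 219000, 1592000, 2769000, 0.0088 / (2 * 219000),
    "x_inv", 607000, 365000, 1591000, 3321000, 0.0078 / (2 * 365000))
}

#' Build a fully specified truth scenario for synthetic data
#'
#' A scenario bundles everything the synthetic-data generator needs:
#' chromosomes, fixed inversions, the genomic partitioning they induce (via
#' [partition_genome()]), one demographic parameter set per partition, sample
#' sizes per species and the mutation model.  The defaults mimic the study
#' design this package targets: 12 + 9 diploid females, five large
#' alternatively fixed inversions (three overlapping on the X), and
#' partition parameters under which inversions predate the colinear split
#' and receive less migration.
#'
#' @param chromosomes Tibble with `chrom`, `length` (bp), `class`
#'   (`"autosome"` or `"X"`).
#' @param inversions Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and `carrier` (`"A"` or `"B"`, the species fixed for the derived
#'   arrangement).  Use a zero-row tibble for an inversion-free scenario.
#' @param params Optional tibble overriding [default_partition_params()];
#'   must contain one row per partition id with `ne_a`, `ne_b`, `ne_anc`,
#'   `t` (generations) and `m` (per-lineage per-generation migration
#'   probability into species B; 0 gives a DIV history).
#' @param n_a,n_b Diploid sample counts per species (>= 1).
#' @param mu Mutation rate per site per generation.
#' @param gen_time Generation time in years.
#' @param sim_block_length Length of the independently simulated segments
#'   (blocks are unlinked in the generator).
#' @param seed Integer seed stored with the scenario and used as the default
#'   by [sim_dataset()] and [sim_sv_calls()].
#' @return An object of class `inv_scenario`.
#' @examples
#' sc <- sim_scenario(seed = 1)
#' sc$partitions
#' @export
sim_scenario <- function(chromosomes = default_chromosomes(),
                         inversions = default_inversions(),
                         params = NULL, n_a = 12, n_b = 9,
                         mu = 2.8e-9, gen_time = 1,
                         sim_block_length = 64, seed = 0) {
  stopifnot(nrow(chromosomes) >= 1, n_a >= 1, n_b >= 1)
  stop_if_not_scalar_number(mu, "mu", min = 0)
  stop_if_not_scalar_number(gen_time, "gen_time", min = 0)
  if (nrow(inversions)) {
    iv_check(inversions, "inversions")
    len <- setNames(chromosomes$length, chromosomes$chrom)
    if (any(!inversions$chrom %in% chromosomes$chrom) ||
        any(inversions$end > len[inversions$chrom])) {
      stop("inversions must lie inside the declared chromosomes",
           call. = FALSE)
    }
    if (!all(inversions$carrier %in% c("A", "B"))) {
      stop("inversion `carrier` must be 'A' or 'B'", call. = FALSE)
    }
  }
  partitions <- partition_genome(inversions, chromosomes)

  par_tbl <- params %||% default_partition_params()
  need <- unique(partitions$partition)
  # fall back to generic inversion parameters for non-default layouts
  missing_p <- setdiff(need, par_tbl$partition)
  if (length(missing_p)) {
    filler <- par_tbl[par_tbl$partition %in% c("inv_4", "auto_col"), ][1, ]
    extra <- purrr::map_dfr(missing_p, function(p) {
      row <- filler
      row$partition <- p
      row
    })
    par_tbl <- dplyr::bind_rows(par_tbl, extra)
  }
  par_tbl <- par_tbl[match(need, par_tbl$partition), , drop = FALSE]
  for (nm in c("ne_a", "ne_b", "ne_anc", "t", "m")) {
    if (any(!is.finite(par_tbl[[nm]])) || any(par_tbl[[nm]] < 0)) {
      stop("invalid partition parameters in `", nm, "`", call. = FALSE)
    }
  }
  par_tbl$model <- ifelse(par_tbl$m > 0, "im_ab", "div")

  samples <- tibble::tibble(
    sample = c(sprintf("monA%02d", seq_len(n_a)),
               sprintf("flaB%02d", seq_len(n_b))),
    species = rep(c("A", "B"), c(n_a, n_b)))

  structure(list(chromosomes = chromosomes, inversions = inversions,
                 partitions = partitions, params = par_tbl,
                 samples = samples, mu = mu, gen_time = gen_time,
                 sim_block_length = as.integer(sim_block_length),
                 seed = as.integer(seed)),
            class = "inv_scenario")
}

#' @export
print.inv_scenario <- function(x, ...) {
  cat("Synthetic truth scenario\n")
  cat(sprintf("  %d chromosomes (%.2f Mb), %d inversions, %d + %d diploids\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$inversions), sum(x$samples$species == "A"),
              sum(x$samples$species == "B")))
  cat(sprintf("  mu = %g, g = %g yr, seed = %d\n", x$mu, x$gen_time, x$seed))
  print(dplyr::left_join(
    dplyr::count(x$partitions, .data$partition, wt = .data$end - .data$start,
                 name = "bp"),
    x$params, by = "partition"))
  invisible(x)
}
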