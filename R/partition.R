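#' Partition a genome into colinear and inverted regions
#'
#' Applies the partitioning scheme used for inversion dating: colinear
#' autosomal regions (ending at inversion breakpoints) are pooled into one
#' partition because they share an evolutionary history; each autosomal
#' inversion is its own partition; the X colinear region is kept separate
#' from the autosomes; and all (typically overlapping) X inversions are
#' merged into a single partition.
#'
#' @param inversions Tibble with `chrom`, `start`, `end` (0-based
#'   half-open); zero rows allowed.
#' @param chromosomes Tibble with `chrom`, `length` and `class`
#'   (`"autosome"` or `"X"`).
#' @return Tibble with `partition`, `chrom`, `start`, `end`.  Partition ids
#'   are `auto_col`, `inv_<chrom>` (suffixed `_2`, `_3`, ... for multiple
#'   inversions on one autosome), `x_col` and `x_inv`.
#' @examples
#' partition_genome(default_inversions(), default_chromosomes())
#' @export
partition_genome <- function(inversions, chromosomes) {
  stopifnot(all(c("chrom", "length", "class") %in% names(chromosomes)))
  if (!all(chromosomes$class %in% c("autosome", "X"))) {
    stop("chromosome class must be 'autosome' or 'X'", call. = FALSE)
  }
  genome <- tibble::tibble(chrom = chromosomes$chrom, start = 0,
                           end = chromosomes$length)
  cls <- setNames(chromosomes$class, chromosomes$chrom)

  if (nrow(inversions)) {
    iv_check(inversions, "inversions")
    if (any(!inversions$chrom %in% chromosomes$chrom)) {
      stop("inversion on unknown chromosome", call. = FALSE)
    }
  }
  inv <- if (nrow(inversions)) {
    dplyr::mutate(inversions, class = cls[.data$chrom])
  } else {
    tibble::tibble(chrom = character(), start = numeric(),
                   end = numeric(), class = character())
  }

  auto_inv <- inv[inv$class == "autosome", , drop = FALSE]
  x_inv <- inv[inv$class == "X", , drop = FALSE]

  # overlapping autosomal inversions are not interpretable as separate
  # partitions; overlapping X inversions are expected and merged
  if (nrow(auto_inv) > 1) {
    by_chr <- split(auto_inv, auto_inv$chrom)
    for (d in by_chr) {
      if (nrow(d) > 1) {
        d <- d[order(d$start), ]
        if (any(d$start[-1] < d$end[-nrow(d)])) {
          stop("overlapping inversions on autosome ", d$chrom[1],
               call. = FALSE)
        }
      }
    }
  }

  out <- list()
  auto <- genome[cls[genome$chrom] == "autosome", , drop = FALSE]
  if (nrow(auto)) {
    col <- if (nrow(auto_inv)) iv_setdiff(auto, auto_inv) else auto
    if (nrow(col)) out$auto_col <- dplyr::mutate(col, partition = "auto_col")
  }
  if (nrow(auto_inv)) {
    auto_inv <- auto_inv[order(auto_inv$chrom, auto_inv$start), ]
    ids <- paste0("inv_", auto_inv$chrom)
    dup <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids[dup > 1] <- paste0(ids[dup > 1], "_", dup[dup > 1])
    out$auto_inv <- tibble::tibble(partition = ids, chrom = auto_inv$chrom,
                                   start = auto_inv$start,
                                   end = auto_inv$end)
  }
  xg <- genome[cls[genome$chrom] == "X", , drop = FALSE]
  if (nrow(xg)) {
    if (nrow(x_inv)) {
      xm <- iv_reduce(x_inv) # union of overlapping/abutting X inversions
      out$x_inv <- dplyr::mutate(xm, partition = "x_inv")
      xc <- iv_setdiff(xg, xm)
    } else {
      xc <- xg
    }
    if (nrow(xc)) out$x_col <- dplyr::mutate(xc, partition = "x_col")
  }
  res <- dplyr::bind_rows(out)
  dplyr::select(dplyr::arrange(res, .data$chrom, .data$start),
                "partition", "chrom", "start", "end")
}
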