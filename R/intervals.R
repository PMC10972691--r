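# Interval tibbles are 0-based half-open [start, end), one row per interval,
# with an optional `chrom` column.  Set algebra is delegated to IRanges.

iv_check <- function(x, name = "intervals") {
  if (!all(c("start", "end") %in% names(x))) {
    stop(sprintf("`%s` needs `start` and `end` columns", name), call. = FALSE)
  }
  if (any(x$end <= x$start)) {
    stop(sprintf("`%s` has empty or reversed intervals", name), call. = FALSE)
  }
  invisible(x)
}

as_iranges0 <- function(x) {
  IRanges::IRanges(start = as.integer(x$start) + 1L, end = as.integer(x$end))
}

from_iranges0 <- function(ir) {
  tibble::tibble(start = as.numeric(IRanges::start(ir)) - 1,
                 end = as.numeric(IRanges::end(ir)))
}

# apply an IRanges set operation per chromosome
iv_op <- function(x, y, op) {
  x <- iv_check(x); y <- iv_check(y)
  chroms <- union(unique(x$chrom %||% x$chrom), unique(y$chrom))
  if (is.null(x$chrom)) stop("intervals need a `chrom` column", call. = FALSE)
  purrr::map_dfr(sort(unique(c(x$chrom, y$chrom))), function(ch) {
    xi <- as_iranges0(x[x$chrom == ch, , drop = FALSE])
    yi <- as_iranges0(y[y$chrom == ch, , drop = FALSE])
    res <- switch(op,
      intersect = IRanges::intersect(xi, yi),
      setdiff = IRanges::setdiff(xi, yi),
      union = IRanges::union(xi, yi))
    out <- from_iranges0(res)
    tibble::tibble(chrom = rep(ch, nrow(out)), start = out$start,
                   end = out$end)
  })
}

iv_intersect <- function(x, y) iv_op(x, y, "intersect")
iv_setdiff <- function(x, y) iv_op(x, y, "setdiff")
iv_union <- function(x, y) iv_op(x, y, "union")

iv_reduce <- function(x) {
  iv_check(x)
  purrr::map_dfr(sort(unique(x$chrom)), function(ch) {
    out <- from_iranges0(IRanges::reduce(as_iranges0(x[x$chrom == ch, ])))
    tibble::tibble(chrom = rep(ch, nrow(out)), start = out$start,
                   end = out$end)
  })
}

iv_width <- function(x) sum(x$end - x$start)

#' Build a site-class mask with repeats removed
#'
#' Intersects a requested annotation class (for example intergenic intervals)
#' with the complement of a repeat mask, the masking step used before any
#' block-based analysis.  All intervals are 0-based half-open.
#'
#' @param class_intervals Tibble of intervals (`chrom`, `start`, `end`) for the
#'   requested site class (e.g. intergenic sequence).
#' @param repeats Tibble of repeat intervals to exclude; `NULL` for none.
#' @param chrom_lengths Optional named vector of chromosome lengths; intervals
#'   beyond a chromosome end raise an error.
#' @return Tibble of disjoint sorted intervals (`chrom`, `start`, `end`).
#' @examples
#' mask <- site_class_mask(
#'   tibble::tibble(chrom = "2", start = 0, end = 100),
#'   tibble::tibble(chrom = "2", start = 50, end = 60))
#' @export
site_class_mask <- function(class_intervals, repeats = NULL,
                            chrom_lengths = NULL) {
  iv_check(class_intervals, "class_intervals")
  if (!is.null(chrom_lengths)) {
    for (x in list(class_intervals, repeats)) {
      if (is.null(x) || !nrow(x)) next
      bad <- x$end > chrom_lengths[as.character(x$chrom)]
      if (any(is.na(bad)) || any(bad)) {
        stop("intervals extend beyond chromosome ends (or unknown chromosome)",
             call. = FALSE)
      }
    }
  }
  out <- iv_reduce(class_intervals)
  if (!is.null(repeats) && nrow(repeats) && nrow(out)) {
    out <- iv_setdiff(out, repeats)
  }
  if (!nrow(out)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Read / write BED intervals
#'
#' Minimal 3-column BED exchange (0-based half-open), matching the package's
#' internal interval convention.
#'
#' @param path File path.
#' @param x Interval tibble with `chrom`, `start`, `end`.
#' @return `read_bed()` returns a tibble; `write_bed()` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "numeric", "numeric"))
  tibble::as_tibble(x)
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  iv_check(x)
  utils::write.table(x[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
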