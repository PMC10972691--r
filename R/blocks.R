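#' Cut callable intervals into fixed-length blocks
#'
#' Packs callable sites greedily from left to right into blocks of exactly
#' `block_length` callable sites.  A candidate block whose genomic span
#' exceeds `max_span` is discarded and packing restarts at the next callable
#' site; trailing sites that cannot fill a block are discarded.
#'
#' @param intervals Tibble of sorted disjoint callable intervals (`start`,
#'   `end`, 0-based half-open) on one chromosome.
#' @param block_length Callable sites per block (64 or 128 in typical use).
#' @param max_span Maximum genomic span (bp) a block may cover (default
#'   `2 * block_length`).
#' @return Tibble with one row per block sub-interval: `block` (integer
#'   id), `start`, `end`.  A block spans one or more sub-intervals whose
#'   total width is exactly `block_length`.
#' @examples
#' cut_blocks(tibble::tibble(start = 0, end = 192), block_length = 64)
#' @export
cut_blocks <- function(intervals, block_length = 64,
                       max_span = 2 * block_length) {
  iv_check(intervals, "intervals")
  stopifnot(block_length >= 1, max_span >= block_length)
  iv <- dplyr::arrange(intervals, .data$start)
  if (any(head(iv$end, -1) > tail(iv$start, -1))) {
    stop("callable intervals must be disjoint", call. = FALSE)
  }
  n_sites <- sum(iv$end - iv$start)
  if (n_sites < block_length) {
    return(tibble::tibble(block = integer(), start = numeric(),
                          end = numeric()))
  }
  pos <- unlist(purrr::map2(iv$start, iv$end, function(s, e) seq(s, e - 1)))

  starts <- integer(0) # first-site index of each accepted block
  i <- 1L
  while (i + block_length - 1L <= n_sites) {
    span <- pos[i + block_length - 1L] - pos[i] + 1
    if (span <= max_span) {
      starts <- c(starts, i)
      i <- i + block_length
    } else {
      i <- i + 1L
    }
  }
  if (!length(starts)) {
    return(tibble::tibble(block = integer(), start = numeric(),
                          end = numeric()))
  }
  # convert each block's callable sites back to genomic sub-intervals
  purrr::map_dfr(seq_along(starts), function(b) {
    p <- pos[starts[b]:(starts[b] + block_length - 1L)]
    cut <- c(0L, which(diff(p) > 1), length(p))
    tibble::tibble(block = b,
                   start = p[head(cut, -1) + 1L],
                   end = p[cut[-1]] + 1)
  })
}

#' Classify a biallelic site for a heterospecific pair of diploids
#'
#' Maps the two genotypes onto the four folded blockwise mutation types:
#' `hetA` (A heterozygous, B homozygous), `hetB` (the reverse), `hetAB`
#' (both heterozygous for the same two alleles), `fixed` (homozygous for
#' different alleles), `mono` (identical homozygotes) or `missing`.  The
#' classification is symmetric under allele relabelling.
#'
#' @param gt_a,gt_b Genotypes of the A and B individual: either strings
#'   like `"C/T"` (any separator `/` or `|`) or derived-allele dosages 0, 1,
#'   2.  Vectorized; `NA` gives `missing`.
#' @return Factor with levels `mono`, `hetA`, `hetB`, `hetAB`, `fixed`,
#'   `missing`.
#' @examples
#' classify_site(c("C/C", "C/T", "C/T"), c("T/T", "T/T", "C/T"))
#' @export
classify_site <- function(gt_a, gt_b) {
  lv <- c("mono", "hetA", "hetB", "hetAB", "fixed", "missing")
  if (is.character(gt_a) || is.character(gt_b)) {
    parse1 <- function(g) strsplit(as.character(g), "[/|]")
    aa <- parse1(gt_a)
    bb <- parse1(gt_b)
    out <- character(length(aa))
    for (i in seq_along(aa)) {
      al <- aa[[i]]; bl <- bb[[i]]
      if (anyNA(al) || anyNA(bl) || length(al) != 2L || length(bl) != 2L ||
          any(al == ".") || any(bl == ".")) {
        out[i] <- "missing"
        next
      }
      alleles <- unique(c(al, bl))
      if (length(alleles) > 2L) {
        stop("more than two alleles across the pair at element ", i,
             call. = FALSE)
      }
      ha <- al[1] != al[2]
      hb <- bl[1] != bl[2]
      out[i] <- if (ha && hb) "hetAB" else if (ha) "hetA" else if (hb) "hetB"
      else if (al[1] != bl[1]) "fixed" else "mono"
    }
    return(factor(out, levels = lv))
  }
  da <- as.integer(gt_a)
  db <- as.integer(gt_b)
  out <- rep("missing", length(da))
  known <- !is.na(da) & !is.na(db)
  out[known & da == 1L & db == 1L] <- "hetAB"
  out[known & da == 1L & db != 1L] <- "hetA"
  out[known & db == 1L & da != 1L] <- "hetB"
  out[known & da != 1L & db != 1L & abs(da - db) == 2L] <- "fixed"
  out[known & da != 1L & db != 1L & da == db] <- "mono"
  factor(out, levels = lv)
}

#' Per-block mutation-type counts for heterospecific sample pairs
#'
#' The workhorse between a genotype dataset and the bSFS: intersects the
#' requested site-class mask (minus repeats) with each genomic partition,
#' cuts the callable sequence into blocks of `block_length` callable sites,
#' and tallies the four mutation types per block for every (or a subset of)
#' heterospecific sample pair.  Blocks containing a missing genotype for a
#' pair are dropped for that pair (count recorded in the `n_dropped`
#' attribute).
#'
#' @param dataset An `inv_dataset` (or compatible list with `genotypes`,
#'   `annotation`, `repeats`, `samples`, `chromosomes`).
#' @param partitions Tibble from [partition_genome()]; defaults to the
#'   dataset's truth partitioning when available, else one partition per
#'   chromosome.
#' @param site_class Annotation class to analyze (default `"intergenic"`);
#'   repeats are always excluded.
#' @param block_length,max_span See [cut_blocks()].
#' @param pairs Optional two-column tibble/data frame (`sample_a`,
#'   `sample_b`) of pairs to use; default all A x B pairs.
#' @param max_pairs Optional cap on the number of pairs (first `max_pairs`
#'   of the Cartesian grid), to bound compute.
#' @return Tibble with `partition`, `chrom`, `block`, `start`, `end`
#'   (block span), `sample_a`, `sample_b`, `hetA`, `hetB`, `hetAB`,
#'   `fixed`.  Attributes: `block_length`, `n_dropped`.
#' @export
block_counts <- function(dataset, partitions = NULL,
                         site_class = "intergenic", block_length = 64,
                         max_span = 2 * block_length, pairs = NULL,
                         max_pairs = Inf) {
  partitions <- partitions %||%
    dataset$provenance$scenario$partitions %||%
    tibble::tibble(partition = dataset$chromosomes$chrom,
                   chrom = dataset$chromosomes$chrom, start = 0,
                   end = dataset$chromosomes$length)
  ann <- dataset$annotation[dataset$annotation$class == site_class, ]
  mask <- site_class_mask(ann, dataset$repeats)

  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(
      sample_a = dataset$samples$sample[dataset$samples$species == "A"],
      sample_b = dataset$samples$sample[dataset$samples$species == "B"])
  }
  if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), ]

  dos <- genotype_dosage(dataset$genotypes)
  loci <- attr(dos, "loci")

  blocks <- purrr::map_dfr(unique(partitions$partition), function(pid) {
    piv <- partitions[partitions$partition == pid, ]
    callable <- iv_intersect(mask, piv)
    purrr::map_dfr(unique(callable$chrom), function(ch) {
      bl <- cut_blocks(callable[callable$chrom == ch, ], block_length,
                       max_span)
      if (!nrow(bl)) return(tibble::tibble())
      dplyr::mutate(bl, chrom = ch, partition = pid)
    })
  })
  if (!nrow(blocks)) {
    stop("no blocks could be formed; check masks and block_length",
         call. = FALSE)
  }
  blocks$.bid <- paste(blocks$partition, blocks$chrom, blocks$block)

  # block summary (one row per block)
  bsum <- dplyr::summarise(
    dplyr::group_by(blocks, .data$partition, .data$chrom, .data$block,
                    .data$.bid),
    start = min(.data$start), end = max(.data$end), .groups = "drop")

  # assign variant sites to blocks (0-based positions)
  hit <- if (nrow(loci)) {
    purrr::map_dfr(unique(blocks$chrom), function(ch) {
      vb <- which(loci$chrom == ch)
      if (!length(vb)) return(tibble::tibble())
      bl <- blocks[blocks$chrom == ch, ]
      ir_v <- IRanges::IRanges(start = loci$pos[vb], width = 1L) # 1-based
      ir_b <- IRanges::IRanges(start = bl$start + 1L, end = bl$end)
      ov <- IRanges::findOverlaps(ir_v, ir_b)
      tibble::tibble(vrow = vb[S4Vectors::queryHits(ov)],
                     .bid = bl$.bid[S4Vectors::subjectHits(ov)])
    })
  } else tibble::tibble(vrow = integer(), .bid = character())

  n_dropped <- 0L
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    res <- bsum
    res$sample_a <- pairs$sample_a[k]
    res$sample_b <- pairs$sample_b[k]
    cnt <- matrix(0L, nrow(res), 4L,
                  dimnames = list(res$.bid, mutation_types))
    miss <- rep(FALSE, nrow(res))
    if (nrow(hit)) {
      cl <- classify_site(dos[hit$vrow, pairs$sample_a[k]],
                          dos[hit$vrow, pairs$sample_b[k]])
      tt <- table(factor(hit$.bid, levels = res$.bid), cl)
      cnt[, ] <- tt[, mutation_types]
      miss <- tt[, "missing"] > 0
    }
    res <- dplyr::bind_cols(res, tibble::as_tibble(cnt))
    n_dropped <<- n_dropped + sum(miss)
    res[!miss, , drop = FALSE]
  })
  out$.bid <- NULL
  attr(out, "block_length") <- as.integer(block_length)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Tally per-block counts into a truncated bSFS
#'
#' Aggregates per-block, per-pair mutation-type counts into the blockwise
#' site frequency spectrum: counts above `kmax` collapse into a residual
#' class per type (coded `kmax + 1`), and the total block count is
#' conserved.
#'
#' @param counts Output of [block_counts()] (or any tibble with `hetA`,
#'   `hetB`, `hetAB`, `fixed` columns, one row per block).
#' @param kmax Truncation level per mutation type (default 2).
#' @param block_length Attached as an attribute (defaults to the input's).
#' @return Tally tibble (`hetA`, `hetB`, `hetAB`, `fixed`, `n`) with
#'   `kmax` and `block_length` attributes.
#' @export
tally_bsfs <- function(counts, kmax = 2,
                       block_length = attr(counts, "block_length")) {
  stopifnot(kmax >= 1)
  m <- as.matrix(counts[, mutation_types])
  new_tally(truncate_counts(m, kmax), kmax,
            block_length %||% NA_integer_)
}
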