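#' Genotype filter policy
#'
#' Collects the genotype-level quality thresholds applied before block
#' cutting: per-sample depth must satisfy `DP >= min_depth` and
#' `DP <= mean + depth_sd_mult * sd` (mean and sd computed per sample from
#' the data, never fixed), read placement balance `RPL >= 1, RPR >= 1`, and
#' strand balance `SAF >= 1, SAR >= 1`.  SNPs within
#' `snp_exclusion_radius` bp of a non-SNP variant are removed entirely.
#'
#' @param min_depth Minimum per-sample read depth (default 8).
#' @param depth_sd_mult Multiplier k in the upper bound `mean + k * sd`
#'   (default 2).
#' @param dp_mode `"upper"` applies `min_depth <= DP <= mean + k * sd`;
#'   `"band"` applies `max(min_depth, mean - k * sd) <= DP <= mean + k * sd`.
#' @param min_rpl,min_rpr,min_saf,min_sar Minimum reads supporting each read
#'   placement/strand class (default 1).
#' @param snp_exclusion_radius Exclusion radius around non-SNP variants, bp.
#' @param on_missing What to do when a FORMAT field is absent from the
#'   data: `"pass"` skips that criterion with a warning, `"error"` stops.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_depth = 8, depth_sd_mult = 2,
                          dp_mode = c("upper", "band"),
                          min_rpl = 1, min_rpr = 1, min_saf = 1, min_sar = 1,
                          snp_exclusion_radius = 2,
                          on_missing = c("pass", "error")) {
  vals <- c(min_depth, depth_sd_mult, min_rpl, min_rpr, min_saf, min_sar,
            snp_exclusion_radius)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all thresholds must be finite and >= 0", call. = FALSE)
  }
  structure(list(min_depth = min_depth, depth_sd_mult = depth_sd_mult,
                 dp_mode = match.arg(dp_mode), min_rpl = min_rpl,
                 min_rpr = min_rpr, min_saf = min_saf, min_sar = min_sar,
                 snp_exclusion_radius = snp_exclusion_radius,
                 on_missing = match.arg(on_missing)),
            class = "filter_policy")
}

#' Decompose variant records into allelic primitives
#'
#' Multi-nucleotide substitutions (REF and ALT of equal length > 1) are
#' split into one SNP per differing position; records with length-changing
#' alleles are classified as non-SNPs and removed.  Multiallelic SNPs (two
#' records leaving different ALT alleles at one position) are dropped, and
#' any SNP within `radius` bp of a base covered by a non-SNP is dropped as
#' well.
#'
#' @param variants Tibble with `chrom`, `pos` (1-based), `ref`, `alt` plus
#'   any extra columns, which are carried to the primitives.
#' @param radius Exclusion radius around non-SNP variants in bp (default 2).
#' @return Tibble of biallelic SNP primitives, with attributes
#'   `non_snps` (tibble of removed non-SNP base positions) and `log`
#'   (named counts of removed records).
#' @examples
#' v <- tibble::tibble(chrom = "2", pos = c(10, 30), ref = c("AT", "C"),
#'                     alt = c("GC", "CTT"))
#' decompose_variants(v)
#' @export
decompose_variants <- function(variants, radius = 2) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  nref <- nchar(variants$ref)
  nalt <- nchar(variants$alt)
  multi <- grepl(",", variants$alt, fixed = TRUE)
  is_snp <- !multi & nref == 1L & nalt == 1L
  is_mnp <- !multi & nref == nalt & nref > 1L
  is_indel <- multi | nref != nalt

  # split MNPs into per-base SNP primitives; .src_pos tracks the parent
  # record so genotype rows can be re-attached
  mnp_rows <- which(is_mnp)
  mnp_prims <- purrr::map_dfr(mnp_rows, function(i) {
    r <- strsplit(variants$ref[i], "")[[1]]
    a <- strsplit(variants$alt[i], "")[[1]]
    d <- which(r != a)
    out <- variants[rep(i, length(d)), , drop = FALSE]
    out$.src_pos <- variants$pos[i]
    out$pos <- variants$pos[i] + d - 1
    out$ref <- r[d]
    out$alt <- a[d]
    out
  })
  plain <- variants[is_snp, , drop = FALSE]
  if (nrow(plain)) plain$.src_pos <- plain$pos
  snps <- dplyr::bind_rows(plain, mnp_prims)
  if (!".src_pos" %in% names(snps)) snps$.src_pos <- snps$pos

  # bases occupied by non-SNP variants
  idl <- variants[is_indel, , drop = FALSE]
  non_snps <- if (nrow(idl)) {
    purrr::map_dfr(seq_len(nrow(idl)), function(i) {
      span <- max(nchar(idl$ref[i]), 1L)
      tibble::tibble(chrom = idl$chrom[i],
                     pos = idl$pos[i] + seq_len(span) - 1)
    })
  } else tibble::tibble(chrom = character(), pos = numeric())

  n0 <- nrow(snps)
  if (nrow(snps) && nrow(non_snps)) {
    zones <- dplyr::transmute(non_snps, chrom = .data$chrom,
                              lo = .data$pos - radius,
                              hi = .data$pos + radius)
    near <- dplyr::inner_join(
      snps[, c("chrom", "pos")], zones,
      by = dplyr::join_by("chrom", dplyr::between("pos", "lo", "hi")))
    keep <- !paste(snps$chrom, snps$pos) %in% paste(near$chrom, near$pos)
    snps <- snps[keep, , drop = FALSE]
  }
  n_near <- n0 - nrow(snps)

  # multiallelic after decomposition: same site, different ALT (or
  # conflicting REF) -> drop the site
  n1 <- nrow(snps)
  if (nrow(snps)) {
    key <- paste(snps$chrom, snps$pos)
    nalleles <- vapply(split(seq_along(key), key), function(ii) {
      length(unique(c(snps$ref[ii], snps$alt[ii])))
    }, integer(1))
    bad_sites <- names(nalleles)[nalleles > 2 |
                                   tabulate(factor(key, names(nalleles)),
                                            length(nalleles)) > 1]
    snps <- snps[!key %in% bad_sites, , drop = FALSE]
  }
  snps <- dplyr::arrange(snps, .data$chrom, .data$pos)
  attr(snps, "non_snps") <- non_snps
  attr(snps, "log") <- c(non_snp = sum(is_indel),
                         near_non_snp = n_near,
                         multiallelic = n1 - nrow(snps))
  snps
}

#' Per-sample depth statistics
#'
#' Mean and standard deviation of `dp` per sample over sites with a depth
#' value, used for the data-driven upper depth bound.
#'
#' @param genotypes Long genotype tibble with `sample` and `dp` columns.
#' @return Tibble with `sample`, `mean_dp`, `sd_dp`.
#' @export
coverage_stats <- function(genotypes) {
  dplyr::summarise(dplyr::group_by(genotypes, .data$sample),
                   mean_dp = mean(.data$dp, na.rm = TRUE),
                   sd_dp = sd(.data$dp, na.rm = TRUE), .groups = "drop")
}

#' Apply genotype-level quality filters
#'
#' Sets genotypes violating the [filter_policy()] thresholds to missing
#' (`NA`).  Filtering is idempotent and monotone: stricter thresholds never
#' increase the number of callable genotypes.
#'
#' @param genotypes Long genotype tibble (`chrom`, `pos`, `sample`, `gt`)
#'   with optional `dp`, `rpl`, `rpr`, `saf`, `sar` columns.
#' @param policy A [filter_policy()].
#' @param stats Optional precomputed [coverage_stats()]; computed from the
#'   data when `NULL`.
#' @return The genotype tibble with failing genotypes set to `NA` and an
#'   attribute `n_filtered` (number of genotypes newly set missing).
#' @export
filter_genotypes <- function(genotypes, policy = filter_policy(),
                             stats = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  have <- intersect(c("dp", "rpl", "rpr", "saf", "sar"), names(genotypes))
  missing_fields <- setdiff(c("dp", "rpl", "rpr", "saf", "sar"), have)
  if (length(missing_fields)) {
    msg <- paste("FORMAT fields absent, criteria skipped:",
                 paste(missing_fields, collapse = ", "))
    if (policy$on_missing == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  bad <- rep(FALSE, nrow(genotypes))
  if ("dp" %in% have) {
    stats <- stats %||% coverage_stats(genotypes)
    up <- stats$mean_dp + policy$depth_sd_mult * stats$sd_dp
    lo <- if (policy$dp_mode == "band") {
      pmax(policy$min_depth, stats$mean_dp - policy$depth_sd_mult * stats$sd_dp)
    } else rep(policy$min_depth, nrow(stats))
    i <- match(genotypes$sample, stats$sample)
    bad <- bad | genotypes$dp < lo[i] | genotypes$dp > up[i]
  }
  for (f in c("rpl", "rpr", "saf", "sar")) {
    if (f %in% have) {
      bad <- bad | genotypes[[f]] < policy[[paste0("min_", f)]]
    }
  }
  bad[is.na(bad)] <- TRUE # missing quality values fail closed
  out <- genotypes
  n_before <- sum(is.na(out$gt))
  out$gt[bad] <- NA_character_
  attr(out, "n_filtered") <- sum(is.na(out$gt)) - n_before
  attr(out, "coverage_stats") <- stats
  out
}

#' Preprocess raw variants: decompose, filter, report
#'
#' Convenience wrapper chaining [decompose_variants()] and
#' [filter_genotypes()]: genotype rows are re-attached to the SNP
#' primitives by record position before filtering.
#'
#' @inheritParams decompose_variants
#' @inheritParams filter_genotypes
#' @return List with `variants` (clean SNP primitives), `genotypes`
#'   (filtered long tibble restricted to those primitives) and `log`.
#' @export
preprocess_variants <- function(variants, genotypes,
                                policy = filter_policy()) {
  snps <- decompose_variants(variants, radius = policy$snp_exclusion_radius)
  # genotypes of an MNP record apply to each of its primitives
  prim <- dplyr::select(snps, "chrom", new_pos = "pos", pos = ".src_pos")
  gt <- dplyr::inner_join(genotypes, prim, by = c("chrom", "pos"),
                          relationship = "many-to-many")
  gt$pos <- gt$new_pos
  gt$new_pos <- NULL
  gt <- filter_genotypes(gt, policy)
  out_snps <- dplyr::select(snps, -".src_pos")
  attr(out_snps, "non_snps") <- attr(snps, "non_snps")
  attr(out_snps, "log") <- attr(snps, "log")
  list(variants = out_snps, genotypes = gt,
       log = list(decompose = attr(snps, "log"),
                  n_filtered = attr(gt, "n_filtered")))
}
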