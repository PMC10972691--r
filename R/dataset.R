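#' Generate a synthetic genotype dataset from a truth scenario
#'
#' Simulates diploid genotypes for every sample in the scenario by drawing,
#' for each fixed-length segment of each partition, an independent genealogy
#' from the n-lineage two-deme structured coalescent with that partition's
#' IM (or DIV) parameters, and dropping infinite-sites mutations.  Also lays
#' down deterministic annotation masks (intergenic/intronic/coding and
#' repeats in a repeating 1-kb pattern) so downstream site-class filtering
#' retains a known fraction of sites, and records provenance.
#'
#' Migration bookkeeping: a scenario migration probability `m > 0` means
#' forwards-time introgression from species A into species B, so backwards
#' in time lineages sampled in B migrate into A.
#'
#' @param scenario An `inv_scenario` from [sim_scenario()].
#' @param seed Integer seed (default: the scenario's seed).  Regeneration
#'   with the same scenario and seed is identical.
#' @return An object of class `inv_dataset`: a list with `variants`
#'   (tibble `chrom`, `pos` 1-based, `ref`, `alt`, `partition`), `genotypes`
#'   (long tibble `chrom`, `pos`, `sample`, `gt` with `"0/0"`, `"0/1"`,
#'   `"1/1"`), `annotation`, `repeats`, `inversions`, `samples`,
#'   `chromosomes` and `provenance`.
#' @examples
#' sc <- sim_scenario(chromosomes = default_chromosomes(20000),
#'                    inversions = default_inversions()[0, ], seed = 1)
#' ds <- sim_dataset(sc)
#' nrow(ds$variants)
#' @export
sim_dataset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "inv_scenario"))
  if (any(scenario$chromosomes$length <= 0)) {
    stop("zero-length chromosome", call. = FALSE)
  }
  bl <- scenario$sim_block_length
  n_a <- sum(scenario$samples$species == "A")
  n_b <- sum(scenario$samples$species == "B")

  sims <- with_seed_if(seed, {
    purrr::map(unique(scenario$partitions$partition), function(pid) {
      iv <- scenario$partitions[scenario$partitions$partition == pid, ]
      pp <- as.list(scenario$params[scenario$params$partition == pid, ])
      nref <- pp$ne_anc
      coalA <- nref / pp$ne_a
      coalB <- nref / pp$ne_b
      migBA <- if (pp$model == "im_ab") 2 * nref * pp$m else 0
      Tsc <- pp$t / (2 * nref)

      # segment the partition's intervals into simulation blocks; trailing
      # remainders become shorter blocks so the whole interval is covered
      segs <- purrr::map_dfr(seq_len(nrow(iv)), function(i) {
        len <- iv$end[i] - iv$start[i]
        nb <- len %/% bl
        starts <- iv$start[i] + bl * seq_len(nb) - bl
        widths <- rep.int(bl, nb)
        if (len %% bl > 0) {
          starts <- c(starts, iv$start[i] + nb * bl)
          widths <- c(widths, len %% bl)
        }
        tibble::tibble(chrom = iv$chrom[i], start = starts, width = widths)
      })

      parts <- purrr::map(unique(segs$width), function(w) {
        sg <- segs[segs$width == w, , drop = FALSE]
        sim <- sim_blocks_cpp(nrow(sg), as.integer(w), n_a, n_b, coalA,
                              coalB, migBA, 0, Tsc, 1,
                              2 * nref * scenario$mu * w)
        if (!length(sim$block)) return(NULL)
        list(tab = tibble::tibble(chrom = sg$chrom[sim$block + 1L],
                                  pos = sg$start[sim$block + 1L] + sim$site + 1,
                                  partition = pid),
             dos = sim$dosage)
      })
      parts <- purrr::compact(parts)
      if (!length(parts)) return(NULL)
      list(tab = dplyr::bind_rows(purrr::map(parts, "tab")),
           dos = do.call(rbind, purrr::map(parts, "dos")))
    })
  })
  sims <- purrr::compact(sims)
  tab <- dplyr::bind_rows(purrr::map(sims, "tab"))
  dos <- do.call(rbind, purrr::map(sims, "dos"))

  nucs <- c("A", "C", "G", "T")
  if (is.null(dos) || !nrow(tab)) {
    variants <- tibble::tibble(chrom = character(), pos = numeric(),
                               ref = character(), alt = character(),
                               partition = character())
    genotypes <- tibble::tibble(chrom = character(), pos = numeric(),
                                sample = character(), gt = character())
  } else {
    ord <- order(tab$chrom, tab$pos)
    tab <- tab[ord, , drop = FALSE]
    dos <- dos[ord, , drop = FALSE]
    colnames(dos) <- scenario$samples$sample
    variants <- with_seed_if(if (is.null(seed)) NULL else seed + 1L, {
      ref <- sample(nucs, nrow(tab), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), "")
      tibble::tibble(chrom = tab$chrom, pos = tab$pos, ref = ref,
                     alt = unname(alt), partition = tab$partition)
    })
    genotypes <- tidyr::pivot_longer(
      dplyr::bind_cols(variants[, c("chrom", "pos")],
                       tibble::as_tibble(matrix(c("0/0", "0/1", "1/1")[dos + 1L],
                                                nrow = nrow(dos),
                                                dimnames = dimnames(dos)))),
      cols = -c("chrom", "pos"), names_to = "sample", values_to = "gt")
  }

  masks <- build_masks(scenario$chromosomes)
  structure(list(variants = variants, genotypes = genotypes,
                 annotation = masks$annotation, repeats = masks$repeats,
                 inversions = scenario$inversions,
                 samples = scenario$samples,
                 chromosomes = scenario$chromosomes,
                 provenance = list(scenario = scenario, seed = seed)),
            class = "inv_dataset")
}

# deterministic repeating 1-kb annotation pattern:
#   [0,600) intergenic, [600,650) intronic, [650,800) coding,
#   [800,1000) intergenic, repeats [500,650)
# => intergenic minus repeats covers 700/1000 = 70% of each chromosome
build_masks <- function(chromosomes) {
  tile <- function(len, a, b) {
    k <- seq(0, len - 1, by = 1000)
    tibble::tibble(start = pmin(k + a, len), end = pmin(k + b, len)) %>%
      dplyr::filter(.data$end > .data$start)
  }
  ann <- purrr::map_dfr(seq_len(nrow(chromosomes)), function(i) {
    len <- chromosomes$length[i]
    dplyr::bind_rows(
      dplyr::mutate(dplyr::bind_rows(tile(len, 0, 600), tile(len, 800, 1000)),
                    class = "intergenic"),
      dplyr::mutate(tile(len, 600, 650), class = "intronic"),
      dplyr::mutate(tile(len, 650, 800), class = "coding")) %>%
      dplyr::mutate(chrom = chromosomes$chrom[i])
  })
  rep <- purrr::map_dfr(seq_len(nrow(chromosomes)), function(i) {
    dplyr::mutate(tile(chromosomes$length[i], 500, 650),
                  chrom = chromosomes$chrom[i])
  })
  list(annotation = dplyr::select(dplyr::arrange(ann, .data$chrom, .data$start),
                                  "chrom", "start", "end", "class"),
       repeats = dplyr::select(rep, "chrom", "start", "end"))
}

#' @export
print.inv_dataset <- function(x, ...) {
  cat("Synthetic dataset\n")
  cat(sprintf("  %d variants, %d samples, %d chromosomes (seed %s)\n",
              nrow(x$variants), nrow(x$samples), nrow(x$chromosomes),
              format(x$provenance$seed)))
  invisible(x)
}

#' Genotype dosage matrix of a dataset
#'
#' Pivots the long genotype tibble into a variant-by-sample matrix of
#' derived-allele dosages (0, 1, 2; `NA` for missing genotypes), the
#' representation used by block counting.
#'
#' @param genotypes Long genotype tibble (`chrom`, `pos`, `sample`, `gt`).
#' @return Integer matrix with one row per `chrom:pos` and one column per
#'   sample; rows are ordered as in `dplyr::distinct(chrom, pos)`.
#' @export
genotype_dosage <- function(genotypes) {
  wide <- tidyr::pivot_wider(genotypes, id_cols = c("chrom", "pos"),
                             names_from = "sample", values_from = "gt")
  gt <- as.matrix(wide[, -(1:2), drop = FALSE])
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt == "1/1"] <- 2L
  attr(dos, "loci") <- wide[, 1:2]
  dos
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `synthetic.vcf` (VCFv4.2, unphased diploid GT, one ALT per
#' record), `intergenic.bed`, `repeats.bed`, `inversions.bed`,
#' `samples.tsv` and `truth.json` (scenario parameters and seed) into a
#' directory.  Output is deterministic for a given dataset.
#'
#' @param dataset An `inv_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "inv_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dos <- genotype_dosage(dataset$genotypes)
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos),
               dimnames = dimnames(dos))
  gt[is.na(gt)] <- "./."
  v <- dataset$variants
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>",
                      dataset$chromosomes$chrom, dataset$chromosomes$length),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- if (nrow(v)) {
    paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), ".",
          v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(header, body), file.path(dir, "synthetic.vcf"))

  ig <- dataset$annotation[dataset$annotation$class == "intergenic", ]
  write_bed(ig, file.path(dir, "intergenic.bed"))
  write_bed(dataset$repeats, file.path(dir, "repeats.bed"))
  if (nrow(dataset$inversions)) {
    write_bed(dataset$inversions, file.path(dir, "inversions.bed"))
  }
  utils::write.table(dataset$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- dataset$provenance$scenario
  jsonlite::write_json(
    list(seed = dataset$provenance$seed, mu = sc$mu, gen_time = sc$gen_time,
         params = sc$params, partitions = sc$partitions),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read variant records and genotypes from a VCF file
#'
#' Thin wrapper over `vcfR` returning the package's long genotype
#' representation.  Multi-allelic records are kept as-is (one ALT string);
#' use [decompose_variants()] downstream.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return List with `variants` (tibble `chrom`, `pos`, `ref`, `alt`) and
#'   `genotypes` (long tibble `chrom`, `pos`, `sample`, `gt`).
#' @export
read_variants <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variants() needs the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  variants <- tibble::tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                             ref = fix$REF, alt = fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  genotypes <- tidyr::pivot_longer(
    dplyr::bind_cols(variants[, c("chrom", "pos")],
                     tibble::as_tibble(as.data.frame(gt, stringsAsFactors = FALSE))),
    cols = -c("chrom", "pos"), names_to = "sample", values_to = "gt")
  genotypes$gt[genotypes$gt %in% c("./.", ".")] <- NA_character_
  list(variants = variants, genotypes = genotypes)
}
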