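test_that("block cutting packs callable sites with the span rule", {
  # 192 contiguous callable sites -> 3 blocks of 64
  b <- cut_blocks(tibble::tibble(start = 0, end = 192), 64)
  expect_equal(max(b$block), 3)
  expect_equal(sum(b$end - b$start), 3 * 64)

  # 64th site lies 1 kb away: every candidate violates max_span -> 0 blocks
  b2 <- cut_blocks(tibble::tibble(start = c(0, 1000), end = c(60, 1010)),
                   64, max_span = 128)
  expect_equal(nrow(b2), 0)

  # abutting intervals concatenate into one block spanning [0, 64)
  b3 <- cut_blocks(tibble::tibble(start = c(0, 63), end = c(63, 64)), 64)
  expect_equal(unique(b3$block), 1L)
  expect_equal(c(min(b3$start), max(b3$end)), c(0, 64))

  # a gap inside max_span is bridged; the block still has 64 callable sites
  b4 <- cut_blocks(tibble::tibble(start = c(0, 40), end = c(32, 72)), 64)
  expect_equal(sum(b4$end - b4$start), 64)
  expect_equal(max(b4$end) - min(b4$start), 72)
})

test_that("site classification matches haplotype-pair enumeration and folds", {
  expect_equal(as.character(classify_site("C/C", "T/T")), "fixed")
  expect_equal(as.character(classify_site("C/T", "C/T")), "hetAB")
  expect_equal(as.character(classify_site("C/C", "C/C")), "mono")
  expect_equal(as.character(classify_site(NA, "C/C")), "missing")
  expect_error(classify_site("C/T", "G/A"), "two alleles")

  # oracle: enumerate the four haplotype subsets a mutation can subtend in
  # (a1,a2) x (b1,b2); "C/T vs T/T" has the minor allele on one A lineage
  gt_a <- c("C/T", "T/T", "C/T", "C/C")
  gt_b <- c("T/T", "C/T", "C/T", "T/T")
  expect_equal(as.character(classify_site(gt_a, gt_b)),
               c("hetA", "hetB", "hetAB", "fixed"))

  # folding: swapping REF/ALT labels leaves every class unchanged
  dos <- tidyr::expand_grid(a = 0:2, b = 0:2)
  expect_equal(classify_site(dos$a, dos$b),
               classify_site(2 - dos$a, 2 - dos$b))
  # symmetry in the pair: swapping species swaps hetA and hetB only
  sw <- as.character(classify_site(dos$b, dos$a))
  orig <- as.character(classify_site(dos$a, dos$b))
  map <- c(mono = "mono", hetA = "hetB", hetB = "hetA", hetAB = "hetAB",
           fixed = "fixed")
  expect_equal(sw, unname(map[orig]))
})

test_that("blockwise counting agrees with per-site brute force", {
  # hand-built dataset: one chromosome, callable [0, 640) -> 10 blocks of 64
  set.seed(31)
  samples <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                            species = c("A", "A", "B", "B"))
  pos <- sort(sample(1:640, 60))
  dos <- matrix(sample(0:2, 60 * 4, replace = TRUE), 60, 4,
                dimnames = list(NULL, samples$sample))
  dos[sample(length(dos), 6)] <- NA # some missing genotypes
  gts <- c("0/0", "0/1", "1/1")
  genotypes <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(chrom = "c1", pos = pos),
                     tibble::as_tibble(matrix(ifelse(is.na(dos), NA,
                                                     gts[dos + 1L]),
                                              60, 4,
                                              dimnames = dimnames(dos)))),
    cols = -c(chrom, pos), names_to = "sample", values_to = "gt")
  ds <- list(genotypes = genotypes,
             annotation = tibble::tibble(chrom = "c1", start = 0, end = 640,
                                         class = "intergenic"),
             repeats = tibble::tibble(chrom = character(), start = numeric(),
                                      end = numeric()),
             samples = samples,
             chromosomes = tibble::tibble(chrom = "c1", length = 1000,
                                          class = "autosome"))
  bc <- block_counts(ds, partitions = tibble::tibble(
    partition = "all", chrom = "c1", start = 0, end = 1000))

  # oracle: classify every site in every block for every pair
  n_checked <- 0
  for (b in 1:10) {
    sel <- pos > (b - 1) * 64 & pos <= b * 64
    for (pa in c("a1", "a2")) for (pb in c("b1", "b2")) {
      da <- dos[sel, pa]
      db <- dos[sel, pb]
      row <- bc[bc$block == b & bc$sample_a == pa & bc$sample_b == pb, ]
      if (any(is.na(da) | is.na(db))) {
        expect_equal(nrow(row), 0) # block dropped for this pair
      } else {
        expect_equal(unlist(row[, c("hetA", "hetB", "hetAB", "fixed")],
                            use.names = FALSE),
                     unname(brute_force_counts(da, db)))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 10)
  expect_gt(attr(bc, "n_dropped"), 0)
})

test_that("tallies conserve block counts and concatenate additively", {
  sc <- small_scenario(len = 20000, n_a = 2, n_b = 2, seed = 22)
  ds <- sim_dataset(sc)
  bc <- block_counts(ds, max_pairs = 2)
  for (k in c(1, 2, 4)) {
    tal <- tally_bsfs(bc, kmax = k)
    expect_equal(sum(tal$n), nrow(bc))
    expect_true(all(as.matrix(tal[, 1:4]) <= k + 1))
  }
  # a block with counts above kmax lands in the residual class
  toy <- tibble::tibble(hetA = 3L, hetB = 0L, hetAB = 0L, fixed = 0L)
  tt <- tally_bsfs(toy, kmax = 2, block_length = 64)
  expect_equal(tt$hetA, 3L) # residual code kmax + 1
  expect_equal(sum(tt$n), 1)

  # concatenation: tally(c(x, y)) = tally(x) + tally(y)
  h <- ceiling(nrow(bc) / 2)
  t1 <- tally_bsfs(bc[1:h, ], kmax = 2)
  t2 <- tally_bsfs(bc[(h + 1):nrow(bc), ], kmax = 2)
  tall <- tally_bsfs(bc, kmax = 2)
  merged <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(t1, t2),
                    hetA, hetB, hetAB, fixed),
    n = sum(n), .groups = "drop")
  expect_equal(dplyr::arrange(tibble::as_tibble(tall), hetA, hetB, hetAB, fixed),
               dplyr::arrange(merged, hetA, hetB, hetAB, fixed),
               ignore_attr = TRUE)
})
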