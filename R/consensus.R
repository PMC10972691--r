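#' Cluster inversion calls from two SV callers
#'
#' Groups INV calls (across callers and samples) into clusters of putatively
#' identical events: two calls belong together when both breakpoints agree
#' within `tol` bp and their reciprocal overlap is at least `min_overlap`
#' (single-linkage within a chromosome).  Mixed SV types never cluster.
#'
#' @param calls A tibble of calls (`chrom`, `start`, `end`, `type`,
#'   `sample`, `species`, `caller`) or a list of such tibbles (e.g. the two
#'   caller tables from [sim_sv_calls()]), which are concatenated.
#' @param tol Breakpoint tolerance in bp (default 1000).
#' @param min_overlap Minimum reciprocal overlap in `(0, 1]` (default 0.8).
#' @return The input calls with a `cluster` id column, plus attribute
#'   `clusters`: one row per cluster with consensus coordinates (medians),
#'   size, per-species carrier counts and caller support.
#' @export
merge_sv_calls <- function(calls, tol = 1000, min_overlap = 0.8) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- dplyr::bind_rows(calls)
  }
  stopifnot(tol >= 0, min_overlap > 0, min_overlap <= 1)
  iv_check(calls, "calls")
  calls <- dplyr::arrange(calls, .data$chrom, .data$start, .data$end)
  n <- nrow(calls)
  if (!n) {
    attr(calls, "clusters") <- tibble::tibble()
    return(calls)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    if (length(idx) < 2) next
    for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
      i <- idx[a]; j <- idx[b]
      if (calls$type[i] != calls$type[j]) next
      if (abs(calls$start[i] - calls$start[j]) > tol) next
      if (abs(calls$end[i] - calls$end[j]) > tol) next
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
      ro <- ov / max(calls$end[i] - calls$start[i],
                     calls$end[j] - calls$start[j])
      if (ov <= 0 || ro < min_overlap) next
      parent[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  calls$cluster <- match(root, unique(root))

  clusters <- dplyr::summarise(
    dplyr::group_by(calls, .data$cluster),
    chrom = .data$chrom[1], type = .data$type[1],
    start = stats::median(.data$start), end = stats::median(.data$end),
    n_callers = dplyr::n_distinct(.data$caller),
    callers = paste(sort(unique(.data$caller)), collapse = ","),
    n_samples_a = dplyr::n_distinct(.data$sample[.data$species == "A"]),
    n_samples_b = dplyr::n_distinct(.data$sample[.data$species == "B"]),
    .groups = "drop")
  clusters$size <- clusters$end - clusters$start
  attr(calls, "clusters") <- clusters
  calls
}

#' Filter clustered SV calls to fixed, species-specific inversions
#'
#' Applies the consensus rule for large alternatively fixed inversions: a
#' cluster is retained when it is supported by both callers, exceeds
#' `min_size`, reaches the species-specific carrier threshold in exactly one
#' species (>= 9 of 12 and >= 6 of 9 in the study design) and is called in
#' at most `max_other` samples of the other species.
#'
#' @param merged Output of [merge_sv_calls()] (calls with a `cluster`
#'   column and a `clusters` attribute).
#' @param min_size Minimum inversion size in bp (default 5e5, i.e. >0.5 Mb).
#' @param min_carriers Named vector: minimum carrier samples per species
#'   (default `c(A = 9, B = 6)`).
#' @param cohort Named vector of cohort sizes (default `c(A = 12, B = 9)`);
#'   carrier counts above these raise an error.
#' @param max_other Maximum samples of the non-carrier species in which the
#'   event may appear (default 1, tolerating isolated caller noise).
#' @return Tibble of consensus inversions: `chrom`, `start`, `end`, `size`,
#'   `species` (carrier), `n_samples_a`, `n_samples_b`, `callers`.
#' @export
consensus_inversions <- function(merged, min_size = 5e5,
                                 min_carriers = c(A = 9, B = 6),
                                 cohort = c(A = 12, B = 9), max_other = 1) {
  cl <- attr(merged, "clusters")
  if (is.null(cl)) stop("run merge_sv_calls() first", call. = FALSE)
  if (!nrow(cl)) return(tibble::tibble())
  if (any(cl$n_samples_a > cohort[["A"]]) ||
      any(cl$n_samples_b > cohort[["B"]])) {
    stop("cluster supported by more samples than the cohort contains",
         call. = FALSE)
  }
  a_fix <- cl$n_samples_a >= min_carriers[["A"]] & cl$n_samples_b <= max_other
  b_fix <- cl$n_samples_b >= min_carriers[["B"]] & cl$n_samples_a <= max_other
  keep <- cl$n_callers >= 2 & cl$size > min_size & cl$type == "INV" &
    xor(a_fix, b_fix)
  out <- cl[keep, , drop = FALSE]
  out$species <- ifelse(a_fix[keep], "A", "B")
  dplyr::arrange(
    dplyr::select(out, "chrom", "start", "end", "size", "species",
                  "n_samples_a", "n_samples_b", "callers"),
    .data$chrom, .data$start)
}
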