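# State spaces for the four-lineage structured coalescent (one diploid
# sampled per species: leaves 1,2 are the haplotypes of the A individual,
# leaves 3,4 of the B individual).  A genealogy state is a set partition of
# the leaves (current lineages) plus, before the split time, a deme label per
# lineage.  Mutation counts per branch-type class are appended as extra state
# dimensions (levels 0..kmax plus a sticky residual), which turns the
# blockwise configuration probability into an absorption distribution.

# branch-type class of the leaf set subtended by a lineage:
# 0 invisible, 1 hetA, 2 hetB, 3 hetAB, 4 fixed
.leaf_class <- function(leaves) {
  nA <- sum(leaves <= 2L)
  nB <- sum(leaves >= 3L)
  if (nA == 2L && nB == 2L) return(0L)
  if (nA == 1L && nB == 1L) return(3L)
  if (nA == 1L) return(1L)
  if (nB == 1L) return(2L)
  4L
}

.canon_state <- function(grp, loc) {
  u <- unique(grp)
  list(grp = match(grp, u), loc = loc[u])
}

.state_key <- function(s) paste(c(s$grp, s$loc), collapse = ".")

# enumerate all (partition, deme-labelling) states reachable under
# coalescence and migration in either direction, with their transitions
.build_geno <- function() {
  if (!is.null(.invdemog_cache$geno)) return(.invdemog_cache$geno)

  states <- list()
  index <- new.env(parent = emptyenv())
  add_state <- function(s) {
    k <- .state_key(s)
    i <- index[[k]]
    if (is.null(i)) {
      states[[length(states) + 1L]] <<- s
      i <- length(states)
      index[[k]] <- i
    }
    i
  }

  init <- list(grp = 1:4, loc = c(1L, 1L, 2L, 2L))
  add_state(init)
  ef <- et <- ety <- integer(0)
  todo <- 1L
  while (todo <= length(states)) {
    s <- states[[todo]]
    ng <- length(s$loc)
    # coalescence of two lineages sharing a deme
    if (ng >= 2L) {
      for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
        if (s$loc[i] != s$loc[j]) next
        grp2 <- s$grp
        grp2[grp2 == j] <- i
        # loc stays indexed by the old labels; .canon_state picks the
        # surviving ones via unique(grp2)
        s2 <- .canon_state(grp2, s$loc)
        k2 <- add_state(s2)
        ef <- c(ef, todo); et <- c(et, k2)
        ety <- c(ety, s$loc[i]) # 1 = coalescence in A, 2 = in B
      }
    }
    # migration of a single lineage
    for (i in seq_len(ng)) {
      loc2 <- s$loc
      loc2[i] <- 3L - loc2[i]
      k2 <- add_state(list(grp = s$grp, loc = loc2))
      ef <- c(ef, todo); et <- c(et, k2)
      ety <- c(ety, if (s$loc[i] == 2L) 3L else 4L) # 3 = B->A (backwards)
    }
    todo <- todo + 1L
  }

  edges1 <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(from = ef, to = et, type = ety),
                    .data$from, .data$to, .data$type),
    mult = dplyr::n(), .groups = "drop")

  class_mult <- function(grp) {
    m <- integer(4)
    for (g in unique(grp)) {
      cl <- .leaf_class(which(grp == g))
      if (cl > 0L) m[cl] <- m[cl] + 1L
    }
    m
  }
  mult1 <- t(vapply(states, function(s) class_mult(s$grp), integer(4)))

  # deme-free partition states for the ancestral phase
  pkeys <- vapply(states, function(s) paste(s$grp, collapse = "."), "")
  p2_keys <- unique(pkeys)
  proj <- match(pkeys, p2_keys)
  p2_grps <- lapply(p2_keys, function(k) as.integer(strsplit(k, ".", fixed = TRUE)[[1]]))
  mult2 <- t(vapply(p2_grps, class_mult, integer(4)))
  ng2 <- vapply(p2_grps, function(g) length(unique(g)), integer(1))

  ef2 <- et2 <- integer(0)
  p2_index <- setNames(seq_along(p2_keys), p2_keys)
  for (p in seq_along(p2_grps)) {
    grp <- p2_grps[[p]]
    k <- length(unique(grp))
    if (k < 2L) next
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      grp2 <- grp
      grp2[grp2 == j] <- i
      grp2 <- match(grp2, unique(grp2))
      k2 <- p2_index[[paste(grp2, collapse = ".")]]
      ef2 <- c(ef2, p); et2 <- c(et2, k2)
    }
  }
  edges2 <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(from = ef2, to = et2, type = 1L),
                    .data$from, .data$to, .data$type),
    mult = dplyr::n(), .groups = "drop")

  g <- list(n1 = length(states), edges1 = edges1, mult1 = mult1,
            init = index[[.state_key(init)]],
            proj = proj, n2 = length(p2_keys), edges2 = edges2,
            mult2 = mult2, ng2 = ng2)
  .invdemog_cache$geno <- g
  g
}

# full product space (genealogy x truncated counts) for a given kmax and
# migration direction; states unreachable under the direction are pruned
.engine_space <- function(kmax, direction = "ab") {
  key <- paste0("space_", kmax, "_", direction)
  if (!is.null(.invdemog_cache[[key]])) return(.invdemog_cache[[key]])
  stopifnot(kmax >= 1L)
  g <- .build_geno()

  allowed <- switch(direction, div = c(1L, 2L), ab = c(1L, 2L, 3L),
                    ba = c(1L, 2L, 4L),
                    stop("unknown direction: ", direction))
  ge <- g$edges1[g$edges1$type %in% allowed, , drop = FALSE]
  reach <- g$init
  repeat {
    nxt <- union(reach, ge$to[ge$from %in% reach])
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  reach <- sort(reach)
  remap <- match(seq_len(g$n1), reach)
  ge <- ge[ge$from %in% reach, , drop = FALSE]
  ge$from <- remap[ge$from]
  ge$to <- remap[ge$to]
  g <- list(n1 = length(reach), edges1 = ge,
            mult1 = g$mult1[reach, , drop = FALSE],
            init = remap[g$init], proj = g$proj[reach],
            n2 = g$n2, edges2 = g$edges2, mult2 = g$mult2, ng2 = g$ng2)
  K <- as.integer(kmax) + 2L
  nc <- K^4L
  lv <- as.matrix(expand.grid(hetA = 0:(K - 1L), hetB = 0:(K - 1L),
                              hetAB = 0:(K - 1L), fixed = 0:(K - 1L)))
  countsum <- rowSums(lv)

  expand_structural <- function(edges, n_states) {
    nge <- nrow(edges)
    list(from = rep.int((edges$from - 1L) * nc, rep(nc, nge)) +
           rep.int(seq_len(nc), nge),
         to = rep.int((edges$to - 1L) * nc, rep(nc, nge)) +
           rep.int(seq_len(nc), nge),
         type = rep.int(edges$type, rep(nc, nge)),
         mult = rep.int(edges$mult, rep(nc, nge)))
  }
  mutation_edges <- function(mult_mat, type_code) {
    out <- list(from = integer(0), to = integer(0), type = integer(0),
                mult = numeric(0))
    for (cl in 1:4) {
      st <- which(mult_mat[, cl] > 0L)
      ok <- which(lv[, cl] < K - 1L) # residual level is sticky
      if (!length(st) || !length(ok)) next
      from <- rep.int((st - 1L) * nc, rep(length(ok), length(st))) +
        rep.int(ok, length(st))
      out$from <- c(out$from, from)
      out$to <- c(out$to, from + K^(cl - 1L))
      out$type <- c(out$type, rep.int(type_code, length(from)))
      out$mult <- c(out$mult,
                    rep.int(as.numeric(mult_mat[st, cl]), rep(length(ok), length(st))))
    }
    out
  }

  s1 <- expand_structural(g$edges1, g$n1)
  m1 <- mutation_edges(g$mult1, 5L)
  e1 <- list(from = c(s1$from, m1$from), to = c(s1$to, m1$to),
             type = c(s1$type, m1$type), mult = c(s1$mult, m1$mult))

  s2 <- expand_structural(g$edges2, g$n2)
  m2 <- mutation_edges(g$mult2, 2L)
  e2 <- list(from = c(s2$from, m2$from), to = c(s2$to, m2$to),
             type = c(s2$type, m2$type), mult = c(s2$mult, m2$mult))
  ord <- order(e2$from)
  e2 <- lapply(e2, function(v) v[ord])
  n2full <- g$n2 * nc
  ptr <- cumsum(c(0L, tabulate(e2$from, nbins = n2full)))

  absorb <- rep.int(-1L, n2full)
  roots <- which(g$ng2 == 1L)
  for (r in roots) absorb[(r - 1L) * nc + seq_len(nc)] <- seq_len(nc) - 1L

  trans <- which(rep(g$ng2, each = nc) > 1L)
  ngf <- rep(g$ng2, each = nc)
  csf <- rep.int(countsum, g$n2)
  topo <- trans[order(-ngf[trans], csf[trans])]

  proj_full <- rep.int((g$proj - 1L) * nc, rep(nc, g$n1)) +
    rep.int(seq_len(nc), g$n1)

  sp <- list(kmax = as.integer(kmax), K = K, nc = nc, lv = lv, geno = g,
             n1full = g$n1 * nc,
             e1_from = e1$from - 1L, e1_to = e1$to - 1L,
             e1_type = e1$type, e1_mult = e1$mult,
             p0 = (g$init - 1L) * nc, # count zero is the first index
             proj = proj_full - 1L, n2full = n2full,
             e2_from = e2$from - 1L, e2_to = e2$to - 1L,
             e2_type = e2$type, e2_mult = e2$mult,
             e2_ptr = as.integer(ptr), topo = topo - 1L, absorb = absorb)
  .invdemog_cache[[key]] <- sp
  sp
}

validate_params <- function(params, model) {
  p <- as.list(params)
  for (nm in c("ne_a", "ne_b", "ne_anc", "t")) {
    stop_if_not_scalar_number(p[[nm]], nm, min = 0)
  }
  if (p$ne_a <= 0 || p$ne_b <= 0 || p$ne_anc <= 0) {
    stop("effective sizes must be positive", call. = FALSE)
  }
  if (model == "div") {
    if (!is.null(p$m) && length(p$m) == 1 && is.finite(p$m) && p$m > 0) {
      stop("the DIV model has no migration; set m = 0 or drop it", call. = FALSE)
    }
    p$m <- 0
  } else {
    stop_if_not_scalar_number(p$m %||% stop("IM models need `m`", call. = FALSE),
                              "m", min = 0)
  }
  p
}

#' Exact blockwise mutation-configuration probabilities
#'
#' Computes the probability of every truncated blockwise mutation
#' configuration (counts of hetA, hetB, hetAB and fixed differences in a
#' block, each capped at `kmax` with a residual class) for one heterospecific
#' pair of diploid genomes under a strict-divergence (DIV) or unidirectional
#' isolation-with-migration (IM) history.  The computation integrates the
#' four-lineage structured coalescent as a finite Markov chain with
#' Poissonized mutation counts: a migration phase of length `t` generations
#' (matrix exponential via uniformization) followed by an ancestral phase run
#' to absorption.  Blocks are assumed free of internal recombination with a
#' constant mutation rate.
#'
#' @param model `"div"`, `"im_ab"` (forwards-time gene flow from species A
#'   into species B; backwards in time, lineages sampled in B migrate into A)
#'   or `"im_ba"`.
#' @param params Named list or one-row data frame with `ne_a`, `ne_b`,
#'   `ne_anc` (diploid effective sizes), `t` (split time in generations) and,
#'   for IM models, `m` (per-lineage per-generation migration probability).
#' @param kmax Per-type truncation of the configuration space (default 2).
#' @param block_length Number of callable sites per block (default 64).
#' @param mu Mutation rate per site per generation (default 2.8e-9).
#' @return A tibble with integer columns `hetA`, `hetB`, `hetAB`, `fixed`
#'   (values `0..kmax` are exact counts, `kmax + 1` is the residual ">kmax"
#'   class) and a `prob` column summing to one.
#' @examples
#' pr <- bsfs_probs("div", list(ne_a = 5e5, ne_b = 5e5, ne_anc = 5e5, t = 1e6))
#' sum(pr$prob)
#' @export
bsfs_probs <- function(model, params, kmax = 2, block_length = 64,
                       mu = 2.8e-9) {
  model <- match.arg(model, c("div", "im_ab", "im_ba"))
  p <- validate_params(params, model)
  stop_if_not_scalar_number(mu, "mu", min = 0)
  sp <- .engine_space(kmax, switch(model, div = "div", im_ab = "ab",
                                   im_ba = "ba"))
  nref <- p$ne_anc
  theta_half <- 2 * nref * mu * block_length
  base1 <- c(nref / p$ne_a, nref / p$ne_b,
             if (model == "im_ab") 2 * nref * p$m else 0,
             if (model == "im_ba") 2 * nref * p$m else 0,
             theta_half)
  base2 <- c(1, theta_half)
  Tscaled <- p$t / (2 * nref)

  pr <- bsfs_engine_cpp(sp$n1full, sp$e1_from, sp$e1_to, sp$e1_type,
                        sp$e1_mult, base1, Tscaled, sp$p0, sp$proj,
                        sp$n2full, sp$e2_from, sp$e2_to, sp$e2_type,
                        sp$e2_mult, base2, sp$e2_ptr, sp$topo, sp$absorb,
                        sp$nc)
  out <- tibble::as_tibble(as.data.frame(sp$lv))
  out$prob <- as.numeric(pr)
  attr(out, "kmax") <- sp$kmax
  attr(out, "block_length") <- as.integer(block_length)
  attr(out, "mu") <- mu
  attr(out, "model") <- model
  attr(out, "params") <- p
  out
}

#' Composite log-likelihood of a bSFS tally
#'
#' `lnCL = sum over configurations of count * log(probability)`, treating
#' blocks as independent.
#'
#' @param tally A bSFS tally as returned by [tally_bsfs()] or [sim_tally()]:
#'   a tibble with `hetA`, `hetB`, `hetAB`, `fixed` and `n` columns.
#' @param probs A configuration probability table from [bsfs_probs()] with
#'   matching `kmax`.
#' @return A single number; `-Inf` (with a warning) if any observed
#'   configuration has zero probability.
#' @export
composite_loglik <- function(tally, probs) {
  kt <- attr(tally, "kmax")
  kp <- attr(probs, "kmax")
  if (!is.null(kt) && !is.null(kp) && kt != kp) {
    stop("tally and probability table use different kmax", call. = FALSE)
  }
  tally <- tally[tally$n > 0, , drop = FALSE]
  j <- dplyr::inner_join(tally, probs, by = mutation_types)
  if (nrow(j) < nrow(tally)) {
    stop("tally contains configurations outside the probability table",
         call. = FALSE)
  }
  if (any(j$n > 0 & j$prob <= 0)) {
    warning("observed configuration with zero probability; lnCL = -Inf")
    return(-Inf)
  }
  sum(j$n * log(j$prob))
}

# truncate raw per-block counts at kmax (code kmax + 1 = residual)
truncate_counts <- function(counts, kmax) {
  pmin(as.matrix(counts), kmax + 1L)
}

# aggregate a matrix of truncated per-block counts into a tally tibble
new_tally <- function(counts, kmax, block_length) {
  df <- tibble::as_tibble(as.data.frame(counts))
  names(df) <- mutation_types
  out <- dplyr::count(df, dplyr::across(dplyr::all_of(mutation_types)),
                      name = "n")
  attr(out, "kmax") <- as.integer(kmax)
  attr(out, "block_length") <- as.integer(block_length)
  out
}
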