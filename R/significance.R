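#' Degree-preserving randomization of a circuit
#'
#' Repeated double-edge swaps on the unit-link multigraph: two unit links
#' (a, b) and (c, d) with all four endpoints distinct are rewired to
#' (a, d) and (c, b) (directed circuits swap targets, preserving weighted
#' in- and out-degrees; undirected swaps preserve weighted degrees).
#' Weights travel with links — parallel units merge into weights.
#' Self-links are never created; proposals that would create one are
#' rejected.
#'
#' @param x A [circuit()] with at least two link units.
#' @param seed Integer seed; swaps are deterministic given it.
#' @param n_swaps Number of attempted swaps; default `10 *` total weight.
#' @return A [circuit()] with the same labels, total weight, and weighted
#'   degree sequence.
#' @export
randomize_degree_preserving <- function(x, seed, n_swaps = NULL) {
  stopifnot(inherits(x, "circuit"))
  M <- total_weight(x)
  if (M < 2) stop("circuit too small to swap (needs at least 2 link units)")
  if (is.null(n_swaps)) n_swaps <- 10L * M
  withr::local_seed(as.integer(seed))
  n <- length(x$labels)
  # unit-link edge list (each weight unit its own row)
  A <- x$A
  idx <- which(if (x$directed) A > 0 else (A > 0 & upper.tri(A)), arr.ind = TRUE)
  src <- rep(idx[, 1], times = A[idx])
  tgt <- rep(idx[, 2], times = A[idx])
  m <- length(src)
  swaps_done <- 0L
  for (s in seq_len(n_swaps)) {
    pick <- sample.int(m, 2L)
    a <- src[pick[1]]; b <- tgt[pick[1]]
    cc <- src[pick[2]]; d <- tgt[pick[2]]
    if (length(unique(c(a, b, cc, d))) < 4L) next
    # rewire (a,b),(c,d) -> (a,d),(c,b)
    tgt[pick[1]] <- d
    tgt[pick[2]] <- b
    swaps_done <- swaps_done + 1L
  }
  if (swaps_done == 0L) {
    warning("no valid swaps were possible; circuit returned unchanged")
    return(x)
  }
  B <- matrix(0, n, n)
  for (k in seq_len(m)) B[src[k], tgt[k]] <- B[src[k], tgt[k]] + 1
  if (!x$directed) B <- B + t(B)
  circuit(B, directed = x$directed, link_type = x$link_type, labels = x$labels)
}

#' Best template epsilon anywhere in a circuit
#'
#' Minimum achievable uncertainty constant for a subgroup template of a
#' given type and sector size, searched over all node subsets (exact for
#' transpositions; greedy growth from every pair for larger templates).
#' Supported types: `"C_2"` (transposition), `"S_k"` (symmetric on k
#' nodes; epsilon is the max pairwise swap cost), `"D_1"` (one involution
#' pairing an even sector), `"C_k"` (cyclic rotation, greedy ordering).
#'
#' @param x A [circuit()].
#' @param type Template tag: `"C_2"`, `"S_k"`, `"D_1"`, or `"C_k"`.
#' @param sector_size Number of nodes moved.
#' @return The minimum epsilon found (numeric scalar).
#' @export
best_template_epsilon <- function(x, type, sector_size) {
  M <- total_weight(x)
  sc <- swap_cost(x)
  n <- length(x$labels)
  type <- if (grepl("^S", type)) "S_k"
          else if (identical(type, "D_1")) "D_1"
          else if (grepl("^D", type)) "C_k"  # dihedral bottleneck: its rotation
          else "C_k"
  if (sector_size == 2) {
    return(min(sc, na.rm = TRUE) / M)
  }
  k <- sector_size
  if (k > n) stop("sector size exceeds circuit size")
  best <- Inf
  # greedy bottleneck subsets seeded from every pair
  pairs <- which(upper.tri(sc), arr.ind = TRUE)
  ord <- order(sc[pairs])
  seeds <- utils::head(ord, 3L * n)
  for (s in seeds) {
    memb <- as.integer(pairs[s, ])
    while (length(memb) < k) {
      rest <- setdiff(seq_len(n), memb)
      add_cost <- vapply(rest, function(r) max(sc[r, memb]), numeric(1))
      memb <- c(memb, rest[which.min(add_cost)])
    }
    eps <- switch(type,
      S_k = max(sc[memb, memb], na.rm = TRUE) / M,
      D_1 = {
        pairing <- greedy_pairing(sc[memb, memb, drop = FALSE])
        inv <- perm_from_cycles(lapply(pairing, function(pr) x$labels[memb[pr]]),
                                x$labels)
        commutator_norm(x, inv) / M
      },
      C_k = {
        cyc <- greedy_cycle(sc[memb, memb, drop = FALSE])
        rot <- perm_from_cycles(list(x$labels[memb[cyc]]), x$labels)
        commutator_norm(x, rot) / M
      },
      stop("unsupported template type: ", type)
    )
    if (eps < best) best <- eps
  }
  best
}

#' p-value of a pseudosymmetry subgroup against the degree-preserving null
#'
#' For each of `R` randomized circuits with the observed circuit's
#' weighted degree sequence, finds the best (minimum-epsilon) subgroup of
#' the same template type and sector size anywhere in the circuit; the
#' p-value is the fraction of null circuits achieving
#' `epsilon* <= observed_eps`. The guarded estimate
#' `(1 + count) / (R + 1)` is also reported.
#'
#' @param x A [circuit()].
#' @param type Template tag as in [best_template_epsilon()].
#' @param sector_size Number of nodes the subgroup moves.
#' @param observed_eps Observed uncertainty constant.
#' @param R Number of null samples (>= 1).
#' @param seed Integer seed for the whole ensemble.
#' @param n_swaps Swaps per randomization (default `10 * M`).
#' @return A `null_result`: `p`, `p_guarded`, `null_eps` (the R sampled
#'   epsilon* values), `observed_eps`, `type`, `sector_size`, `R`,
#'   `seed`.
#' @export
subgroup_pvalue <- function(x, type, sector_size, observed_eps, R = 1000,
                            seed = 1, n_swaps = NULL) {
  stopifnot(R >= 1)
  null_eps <- vapply(seq_len(R), function(r) {
    xr <- randomize_degree_preserving(x, seed = seed + r - 1L, n_swaps = n_swaps)
    best_template_epsilon(xr, type, sector_size)
  }, numeric(1))
  count <- sum(null_eps <= observed_eps + 1e-12)
  structure(
    list(
      p = count / R,
      p_guarded = (1 + count) / (R + 1),
      null_eps = null_eps,
      observed_eps = observed_eps,
      type = type,
      sector_size = sector_size,
      R = R,
      seed = seed
    ),
    class = "null_result"
  )
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf(
    "<null_result> %s on %d nodes: observed eps = %.4f, p = %.4g (guarded %.4g, R = %d)\n",
    x$type, x$sector_size, x$observed_eps, x$p, x$p_guarded, x$R))
  invisible(x)
}

#' @export
tidy.null_result <- function(x, ...) {
  tibble::tibble(
    type = x$type, sector_size = x$sector_size,
    observed_eps = x$observed_eps, p = x$p, p_guarded = x$p_guarded,
    R = x$R, null_eps_min = min(x$null_eps), null_eps_median = stats::median(x$null_eps)
  )
}

#' Weighted degree (strength) sequence of a circuit
#'
#' @param x A [circuit()].
#' @return For undirected circuits a named numeric vector of strengths;
#'   for directed, a tibble with `label`, `out_strength`, `in_strength`.
#' @export
strength_sequence <- function(x) {
  if (x$directed) {
    tibble::tibble(label = x$labels,
                   out_strength = rowSums(x$A),
                   in_strength = colSums(x$A))
  } else {
    stats::setNames(rowSums(x$A), x$labels)
  }
}
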