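#' Louvain modularity partition of a circuit
#'
#' Weighted greedy modularity maximization (Louvain) with multiple
#' seeded restarts; the partition with the best modularity is kept.
#' Directed circuits are symmetrized first (community detection operates
#' on the undirected weighted graph).
#'
#' @param x A connected [circuit()].
#' @param seed Integer seed.
#' @param restarts Number of restarts.
#' @return A named integer vector: community id per label.
#' @export
modularity_partition <- function(x, seed = 1, restarts = 10) {
  stopifnot(inherits(x, "circuit"))
  g <- circuit_igraph(x, force_undirected = TRUE)
  if (!igraph::is_connected(g)) stop("modularity partition requires a connected circuit")
  best <- NULL
  best_q <- -Inf
  withr::local_seed(as.integer(seed))
  for (r in seq_len(restarts)) {
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(cl)
    if (q > best_q) {
      best_q <- q
      best <- cl
    }
  }
  stats::setNames(igraph::membership(best), x$labels)
}

#' Eigenvector centrality by power iteration
#'
#' Principal-eigenvector scores of the weighted adjacency matrix,
#' computed by power iteration and normalized to unit maximum. Nodes in
#' one orbit of an exact automorphism receive equal scores (up to `tol`).
#'
#' @param x A connected [circuit()] with nonnegative weights.
#' @param tol Convergence tolerance on the score vector.
#' @param max_iter Iteration cap.
#' @return A named numeric vector of scores in `[0, 1]`.
#' @export
eigenvector_centrality <- function(x, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(x, "circuit"))
  A <- x$A
  if (x$directed) A <- A + t(A)
  n <- nrow(A)
  # shift by the identity: same principal eigenvector, but the iteration
  # cannot oscillate on bipartite circuits (where +/- lambda pair up)
  A <- A + diag(n)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    w <- A %*% v
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) stop("centrality undefined: zero iterate (disconnected circuit?)")
    w <- as.numeric(w / nrm)
    if (max(abs(w - v)) < tol) {
      return(stats::setNames(w / max(w), x$labels))
    }
    v <- w
  }
  stop("power iteration did not converge in ", max_iter, " iterations")
}

#' Agreement between two partitions
#'
#' Adjusted Rand index between two partitions of the same label
#' universe: 1 for identical partitions, about 0 for independent ones.
#'
#' @param p1,p2 Named vectors (label -> part id) or lists of label sets
#'   over the same universe.
#' @return Numeric score (<= 1).
#' @export
partition_agreement <- function(p1, p2) {
  p1 <- as_membership(p1)
  p2 <- as_membership(p2)
  if (!setequal(names(p1), names(p2))) {
    stop("partitions are over different label universes")
  }
  p2 <- p2[names(p1)]
  mclust::adjustedRandIndex(p1, p2)
}

as_membership <- function(p) {
  if (is.list(p)) {
    labs <- unlist(p)
    if (anyDuplicated(labs)) stop("partition parts overlap")
    memb <- rep(seq_along(p), times = vapply(p, length, integer(1)))
    return(stats::setNames(memb, labs))
  }
  if (is.null(names(p))) stop("membership vector must be named by label")
  stats::setNames(as.integer(factor(p)), names(p))
}

#' Compare symmetry sectors with baseline partitions
#'
#' Scores the sector partition of a factorization against the Louvain
#' modularity partition and (optionally) a functional annotation, using
#' the adjusted Rand index. Neurons outside every sector form one extra
#' part ("fixed").
#'
#' @param x A [circuit()].
#' @param fac A `group_factorization` (or tibble from
#'   [find_pseudosymmetries()] with a `sector` column).
#' @param annotations Optional named vector label -> functional category.
#' @param seed Seed for the modularity baseline.
#' @return A tibble with one row per comparison: `comparison`, `ari`.
#' @export
baseline_comparison <- function(x, fac, annotations = NULL, seed = 1) {
  sectors <- if (inherits(fac, "group_factorization")) {
    lapply(fac$factors, `[[`, "sector")
  } else {
    fac$sector
  }
  memb <- rep(0L, length(x$labels))
  names(memb) <- x$labels
  for (i in seq_along(sectors)) memb[sectors[[i]]] <- i
  lou <- modularity_partition(x, seed = seed)
  out <- tibble::tibble(comparison = "sectors_vs_louvain",
                        ari = partition_agreement(memb, lou))
  if (!is.null(annotations)) {
    ann <- annotations[names(memb)]
    out <- dplyr::bind_rows(out, tibble::tibble(
      comparison = "sectors_vs_annotation",
      ari = partition_agreement(memb, stats::setNames(ann, names(memb)))
    ))
  }
  out
}
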