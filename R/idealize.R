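#' Idealize a circuit under a symmetry group
#'
#' Constructs the ideal (epsilon -> 0) circuit on which every element of
#' the group is an exact automorphism: the adjacency matrix is averaged
#' over the group (`A_hat[i, j]` is the mean of `A[P(i), P(j)]` over all
#' elements P) and then rounded to the nearest integer. Averages are
#' constant on link orbits by construction, and rounding is performed
#' orbit-wise (one rounded value per link orbit, halves rounding up), so
#' exact invariance survives rounding. Per link orbit, the rounded mean
#' minimizes the L1 repair distance among orbit-constant integer
#' matrices.
#'
#' @param x A [circuit()].
#' @param g A materialized [perm_group()] on `x`'s labels.
#' @return An `idealization`: fields `circuit` (the repaired circuit),
#'   `distance` (L1 repair distance in link units), `distance_fraction`
#'   (of the original total weight M), `orbit_table` (tibble: one row per
#'   link orbit with original weights and the idealized value).
#' @export
idealize <- function(x, g) {
  stopifnot(inherits(x, "circuit"), inherits(g, "perm_group"))
  if (is.na(g$order)) stop("group not materialized; call closure() first")
  if (g$order == 0) stop("empty group")
  if (!identical(g$labels, x$labels)) stop("group labels do not match the circuit")
  n <- length(x$labels)
  A <- x$A
  # link orbits: connected components of ordered pairs under the action
  pair_id <- matrix(seq_len(n * n), n, n)
  parent <- seq_len(n * n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (p in g$generators) {  # generator orbits equal group orbits
    img <- unclass(p)
    moved <- which(img != seq_len(n))
    if (!length(moved)) next
    for (i in seq_len(n)) {
      for (jj in seq_len(n)) {
        a <- pair_id[i, jj]
        b <- pair_id[img[i], img[jj]]
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n * n), find, integer(1))
  Ahat <- matrix(0, n, n, dimnames = dimnames(A))
  rows <- list()
  for (r in unique(roots)) {
    cells <- which(roots == r)
    ii <- ((cells - 1L) %% n) + 1L
    jj <- ((cells - 1L) %/% n) + 1L
    keep <- ii != jj
    if (!any(keep)) next
    cells <- cells[keep]; ii <- ii[keep]; jj <- jj[keep]
    mu <- mean(A[cells])
    val <- floor(mu + 0.5)  # half rounds up
    Ahat[cells] <- val
    if (mu != 0 || val != 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        orbit = length(rows) + 1L,
        n_links = length(cells),
        example = paste0(x$labels[ii[1]],
                         if (x$directed) " -> " else " -- ", x$labels[jj[1]]),
        mean_weight = mu,
        ideal_weight = val
      )
    }
  }
  ideal <- circuit(Ahat, directed = x$directed, link_type = x$link_type,
                   labels = x$labels)
  dist_ordered <- sum(abs(A - Ahat))
  dist <- if (x$directed) dist_ordered else dist_ordered / 2
  structure(
    list(
      circuit = ideal,
      distance = dist,
      distance_fraction = dist / max(total_weight(x), 1),
      orbit_table = if (length(rows)) dplyr::bind_rows(rows) else
        tibble::tibble(orbit = integer(0), n_links = integer(0),
                       example = character(0), mean_weight = numeric(0),
                       ideal_weight = numeric(0))
    ),
    class = "idealization"
  )
}

#' @export
print.idealization <- function(x, ...) {
  cat(sprintf(
    "<idealization> repair distance %g link units (%.1f%% of M), %d link orbit(s)\n",
    x$distance, 100 * x$distance_fraction, nrow(x$orbit_table)))
  invisible(x)
}
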