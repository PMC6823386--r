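# Independent oracles used across the suite. These deliberately avoid the
# package's own search code paths.

# Automorphism count via igraph/BLISS: integer link weights are encoded as
# colored edge-subdivision vertices (one dummy vertex per link, colored by
# the weight), so the colored simple graph has exactly the automorphisms
# of the weighted graph. Undirected circuits only.
igraph_automorphism_count <- function(x) {
  stopifnot(!x$directed)
  n <- length(x$labels)
  A <- x$A
  idx <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  n_dummy <- nrow(idx)
  edges <- integer(0)
  for (k in seq_len(n_dummy)) {
    d <- n + k
    edges <- c(edges, idx[k, 1], d, d, idx[k, 2])
  }
  g <- igraph::make_empty_graph(n = n + n_dummy, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  colors <- c(rep(0L, n), as.integer(A[idx]))
  res <- igraph::count_automorphisms(g, colors = colors)
  if (is.list(res)) as.numeric(res$group_size) else as.numeric(res)
}

# Exhaustive n! automorphism filter (n <= 7): brute force over all
# permutations, testing PA = AP entrywise.
brute_force_automorphisms <- function(x) {
  n <- length(x$labels)
  stopifnot(n <= 7)
  perm_rows <- all_permutations(n)
  keep <- list()
  for (r in seq_len(nrow(perm_rows))) {
    img <- perm_rows[r, ]
    if (all(x$A == x$A[img, img])) {
      keep[[length(keep) + 1L]] <- node_perm(img, x$labels)
    }
  }
  keep
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# Brute-force block systems: every partition of the orbit into equal-size
# parts is tested against the block property under all group elements.
brute_force_block_systems <- function(g, orbit) {
  k <- length(orbit)
  parts <- set_partitions(orbit)
  good <- list()
  for (p in parts) {
    sizes <- vapply(p, length, integer(1))
    if (length(unique(sizes)) != 1) next
    ok <- TRUE
    for (el in g$elements) {
      img <- unclass(el)
      for (b in p) {
        bimg <- g$labels[img[match(b, g$labels)]]
        if (length(intersect(bimg, b)) != 0 && !setequal(bimg, b)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) good[[length(good) + 1L]] <- lapply(p, sort)
  }
  good
}

# all set partitions of a label vector (small sets only)
set_partitions <- function(labs) {
  if (length(labs) == 1) return(list(list(labs)))
  first <- labs[1]
  rest <- set_partitions(labs[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

# Adjusted Rand index straight from the contingency-table formula.
ari_oracle <- function(a, b) {
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  tab <- table(a, b)
  comb2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# tiny deterministic weighted test circuit (undirected, heterogeneous)
random_circuit <- function(n, seed, p = 0.4, directed = FALSE, max_w = 3) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && stats::runif(1) < p) A[i, j] <- sample.int(max_w, 1)
      }
    }
    if (!directed) A[lower.tri(A)] <- t(A)[lower.tri(A)]
    circuit(A, directed = directed, labels = paste0("n", seq_len(n)),
            link_type = if (directed) "chemical" else "gap")
  })
}
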