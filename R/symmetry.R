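#' Commutator norm between a permutation and a circuit
#'
#' The L1 norm `||[P, A]|| = sum_ij |A_ij - A_P(i)P(j)|`, which counts the
#' link units where the permutation fails to preserve the wiring, in
#' broken-link units. For undirected circuits the ordered-pair sum is
#' divided by 4: a broken undirected unit link contributes a loss and a
#' gain, each counted in both orientations, and scores exactly 1 — the
#' calibration under which a transposition that misplaces a single unit
#' link in a circuit of 18 weighted links has epsilon 1/18. Directed
#' circuits use the full ordered sum (reversing a directed edge of
#' weight w scores 2w: both ordered entries differ).
#'
#' @param x A [circuit()].
#' @param p A [node_perm()] on `x`'s labels.
#' @return Nonnegative number (integer-valued for integer weights when the
#'   undirected ordered sum is even; a half-integer is possible otherwise).
#' @export
commutator_norm <- function(x, p) {
  stopifnot(inherits(x, "circuit"), inherits(p, "node_perm"))
  if (!identical(attr(p, "labels"), x$labels)) {
    stop("permutation labels do not match the circuit's labels")
  }
  img <- unclass(p)
  s <- sum(abs(x$A - x$A[img, img, drop = FALSE]))
  if (x$directed) s else s / 4
}

#' Is a permutation an exact automorphism?
#'
#' @inheritParams commutator_norm
#' @return `TRUE` iff `commutator_norm(x, p) == 0`, i.e. `PA = AP`.
#' @export
is_automorphism <- function(x, p) {
  commutator_norm(x, p) == 0
}

#' Pseudosymmetry: a permutation with its uncertainty constant
#'
#' Scores a permutation by `epsilon = ||[P, A]|| / M`, the fraction of the
#' circuit's total link weight it fails to preserve. `epsilon = 0` iff the
#' permutation is an exact automorphism; values below 25% are flagged
#' biologically plausible (the animal-to-animal variability of the
#' C. elegans connectome).
#'
#' @inheritParams commutator_norm
#' @param support_only If `TRUE`, normalize by the weight of links incident
#'   to the permutation's support instead of the whole circuit's M.
#' @return A `pseudosymmetry` object with fields `perm`, `norm`, `epsilon`,
#'   `M`, `plausible`.
#' @export
pseudosymmetry <- function(x, p, support_only = FALSE) {
  M <- total_weight(x)
  if (M == 0) stop("empty circuit: total weight is zero")
  if (support_only) {
    sup <- match(perm_support(p), x$labels)
    A <- x$A
    s <- sum(A[sup, , drop = FALSE]) + sum(A[, sup, drop = FALSE]) -
      sum(A[sup, sup, drop = FALSE])
    M <- max(if (x$directed) s else s / 2, 1)
  }
  nrm <- commutator_norm(x, p)
  structure(
    list(perm = p, norm = nrm, epsilon = nrm / M, M = M,
         plausible = nrm / M < 0.25),
    class = "pseudosymmetry"
  )
}

#' @export
print.pseudosymmetry <- function(x, ...) {
  cat(sprintf("<pseudosymmetry> %s  norm = %g, epsilon = %.4f (%s)\n",
              format(x$perm), x$norm, x$epsilon,
              if (x$epsilon == 0) "exact" else if (x$plausible) "plausible" else "implausible"))
  invisible(x)
}

# --- automorphism search -----------------------------------------------

# weighted color refinement: returns integer color per node, stable
refine_colors <- function(A, directed, init = NULL) {
  n <- nrow(A)
  col <- if (is.null(init)) rep(1L, n) else init
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      s <- paste(sort(paste(col[-i], A[i, -i], sep = ":")), collapse = "|")
      if (directed) {
        s <- paste(s, paste(sort(paste(col[-i], A[-i, i], sep = ".")), collapse = "|"))
      }
      paste(col[i], s, sep = "#")
    }, character(1))
    new <- match(sig, unique(sig))
    if (identical(new, col)) return(col)
    col <- new
  }
}

#' Exact automorphism group of a circuit
#'
#' Enumerates all node permutations commuting with the weighted adjacency
#' matrix by backtracking over a color-refined partition: nodes are first
#' partitioned by iterated weighted in/out neighborhood signatures, then a
#' depth-first search assigns images within color classes, pruning on
#' partial adjacency consistency. The full element set is returned up to
#' `order_cap`.
#'
#' @param x A [circuit()].
#' @param max_nodes Size guard; circuits larger than this are rejected with
#'   a suggestion to analyze sectors separately.
#' @param order_cap Abort if more than this many automorphisms are found.
#' @return A [perm_group()] containing every exact automorphism.
#' @export
automorphism_group <- function(x, max_nodes = 64, order_cap = 1e6) {
  stopifnot(inherits(x, "circuit"))
  n <- length(x$labels)
  if (n > max_nodes) {
    stop("circuit has ", n, " nodes (> ", max_nodes,
         "); analyze sectors separately or raise `max_nodes`")
  }
  A <- x$A
  col <- refine_colors(A, x$directed)
  # process nodes grouped by color class, small classes first
  ord <- order(ave(col, col, FUN = length), col, seq_len(n))
  found <- vector("list", 0)
  img <- integer(n)
  used <- logical(n)
  assign_next <- function(k) {
    if (k > n) {
      found[[length(found) + 1L]] <<- img
      if (length(found) > order_cap) stop("automorphism order cap exceeded")
      return(invisible())
    }
    i <- ord[k]
    done <- ord[seq_len(k - 1L)]
    cands <- which(col == col[i] & !used)
    for (j in cands) {
      ok <- all(A[i, done] == A[j, img[done]]) &&
        (!x$directed || all(A[done, i] == A[img[done], j]))
      if (ok) {
        img[i] <<- j
        used[j] <<- TRUE
        assign_next(k + 1L)
        used[j] <<- FALSE
        img[i] <<- 0L
      }
    }
  }
  assign_next(1L)
  elements <- lapply(found, node_perm, labels = x$labels)
  perm_group(elements = elements, labels = x$labels)
}

# --- pairwise swap costs and pseudosymmetry search ----------------------

#' Pairwise transposition cost matrix
#'
#' `swap_cost(x)[i, j]` is the commutator norm of the transposition
#' `(i j)`, in broken-link units. Used to seed the pseudosymmetry search
#' and the null-model template scan.
#'
#' @param x A [circuit()].
#' @return A symmetric numeric matrix with `NA` on the diagonal.
#' @export
swap_cost <- function(x) {
  n <- length(x$labels)
  A <- x$A
  out <- matrix(NA_real_, n, n, dimnames = list(x$labels, x$labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- setdiff(seq_len(n), c(i, j))
      if (x$directed) {
        d <- 2 * (sum(abs(A[i, k] - A[j, k])) + sum(abs(A[k, i] - A[k, j])) +
                    abs(A[i, j] - A[j, i]))
      } else {
        d <- sum(abs(A[i, k] - A[j, k]))
      }
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

#' Search for pseudosymmetries of a circuit
#'
#' Deterministic three-stage search. (1) All exact automorphisms (skipped
#' if the circuit exceeds the size guard). (2) All transpositions with
#' `epsilon <= eps_max`, reported as C_2 candidates. (3) Sector growth:
#' labels whose pairwise swap costs are all within `eps_max * M` are
#' clustered into candidate sectors, and each sector is tested against
#' subgroup templates — the full symmetric group (all transpositions),
#' cyclic rotations (greedy cheapest-ordering), and pairings into a single
#' involution. A template is kept when each of its generators has
#' `epsilon <= eps_max`; the subgroup epsilon reported is the maximum
#' generator epsilon (the mean is also recorded).
#'
#' @param x A [circuit()].
#' @param eps_max Tolerated fraction of broken link weight, in (0, 1].
#' @param max_exact_nodes Size guard for the exact-group stage.
#' @param factorization Optional precomputed `group_factorization` of the
#'   exact automorphism group (avoids recomputing it).
#' @return A tibble with one row per candidate: `template`, `sector`
#'   (list-column of labels), `perm` (list-column of generator
#'   `node_perm`s), `epsilon`, `epsilon_mean`, `norm`, `exact`. Sorted by
#'   epsilon, then support size (descending), then labels.
#' @export
find_pseudosymmetries <- function(x, eps_max = 0.25, max_exact_nodes = 64,
                                  factorization = NULL) {
  stopifnot(inherits(x, "circuit"))
  if (!(eps_max >= 0 && eps_max <= 1)) stop("eps_max must be in [0, 1]")
  M <- total_weight(x)
  if (M == 0) stop("empty circuit")
  n <- length(x$labels)
  rows <- list()
  add_row <- function(template, sector, perms, norms) {
    eps <- norms / M
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      template = template,
      sector = list(sector),
      perm = list(perms),
      epsilon = max(eps),
      epsilon_mean = mean(eps),
      norm = max(norms),
      exact = all(norms == 0)
    )
  }

  # stage 1: exact automorphism group
  if (n <= max_exact_nodes || !is.null(factorization)) {
    fac <- factorization
    if (is.null(fac)) {
      g <- automorphism_group(x)
      fac <- if (group_order(g) > 1) factorize(g) else NULL
    }
    if (!is.null(fac)) {
      for (f in fac$factors) {
        gens <- f$subgroup$generators
        add_row(paste0("exact:", f$name), f$sector, gens,
                vapply(gens, function(p) commutator_norm(x, p), numeric(1)))
      }
    }
  }

  # stage 2: transpositions within tolerance
  sc <- swap_cost(x)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sc[i, j] / M <= eps_max && sc[i, j] > 0) {
        p <- perm_from_cycles(list(x$labels[c(i, j)]), x$labels)
        add_row("C_2", x$labels[c(i, j)], list(p), sc[i, j])
      }
    }
  }

  # stage 3: sector clusters and subgroup templates
  ok <- sc / M <= eps_max
  ok[is.na(ok)] <- FALSE
  comp <- cluster_cliques(ok)
  for (sector_idx in comp) {
    if (length(sector_idx) < 3) next
    sector <- x$labels[sector_idx]
    k <- length(sector_idx)
    # symmetric-group template: all transpositions
    gens <- list()
    norms <- numeric(0)
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        gens[[length(gens) + 1L]] <-
          perm_from_cycles(list(sector[c(a, b)]), x$labels)
        norms <- c(norms, sc[sector_idx[a], sector_idx[b]])
      }
    }
    if (all(norms / M <= eps_max)) add_row(paste0("S_", k), sector, gens, norms)
    # cyclic template: greedy cheapest cycle ordering
    cyc <- greedy_cycle(sc[sector_idx, sector_idx, drop = FALSE])
    rot <- perm_from_cycles(list(sector[cyc]), x$labels)
    nr <- commutator_norm(x, rot)
    if (nr / M <= eps_max) add_row(paste0("C_", k), sector[cyc], list(rot), nr)
    # involution template: greedy min-cost pairing (even sectors)
    if (k %% 2 == 0) {
      pairing <- greedy_pairing(sc[sector_idx, sector_idx, drop = FALSE])
      inv <- perm_from_cycles(lapply(pairing, function(pr) sector[pr]), x$labels)
      ni <- commutator_norm(x, inv)
      if (ni / M <= eps_max) {
        add_row(if (k == 2) "C_2" else "D_1", sector, list(inv), ni)
      }
    }
  }

  if (!length(rows)) {
    return(tibble::tibble(template = character(0), sector = list(),
                          perm = list(), epsilon = numeric(0),
                          epsilon_mean = numeric(0), norm = numeric(0),
                          exact = logical(0)))
  }
  out <- dplyr::bind_rows(rows)
  out$support_size <- vapply(out$sector, length, integer(1))
  out$sector_key <- vapply(out$sector, function(s) paste(sort(s), collapse = ","),
                           character(1))
  out <- dplyr::arrange(out, .data$epsilon, dplyr::desc(.data$support_size),
                        .data$sector_key)
  out <- dplyr::distinct(out, .data$template, .data$sector_key, .keep_all = TRUE)
  dplyr::select(out, -"sector_key")
}

# maximal cliques of mutually-compatible labels, greedily, deterministic:
# grow from each node in index order, adding the smallest-index node
# compatible with all members; emit components of size >= 2 once, deduped.
cluster_cliques <- function(ok) {
  n <- nrow(ok)
  seen <- character(0)
  out <- list()
  for (start in seq_len(n)) {
    memb <- start
    repeat {
      cand <- setdiff(which(apply(ok[, memb, drop = FALSE], 1, all)), memb)
      if (!length(cand)) break
      memb <- sort(c(memb, cand[1]))
    }
    key <- paste(memb, collapse = ",")
    if (length(memb) >= 2 && !key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- memb
    }
  }
  out
}

# greedy cheapest Hamiltonian cycle ordering on a cost submatrix
greedy_cycle <- function(costs) {
  k <- nrow(costs)
  if (k <= 2) return(seq_len(k))
  path <- 1L
  left <- setdiff(seq_len(k), path)
  while (length(left)) {
    nxt <- left[which.min(costs[path[length(path)], left])]
    path <- c(path, nxt)
    left <- setdiff(left, nxt)
  }
  path
}

# greedy min-cost perfect matching on a cost submatrix (even size)
greedy_pairing <- function(costs) {
  k <- nrow(costs)
  left <- seq_len(k)
  pairs <- list()
  while (length(left) > 1) {
    sub <- costs[left, left, drop = FALSE]
    ij <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1L]] <- left[sort(ij)]
    left <- setdiff(left, left[ij])
  }
  pairs
}
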