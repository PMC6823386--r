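#' Build a circulant matrix from its first row
#'
#' Row r+1 is row r shifted one position to the right and wrapped around,
#' so the matrix is determined by `first_row`. The catalogue of filters
#' found in locomotion circuits: `circ(0, 1)` (high-pass), `circ(1, 1)`
#' (low-pass), `circ(0, 1, 0, 1)` (subsampling/oscillation kernel).
#'
#' @param first_row Numeric vector `c_1..c_l`.
#' @return An `l x l` matrix.
#' @export
#' @examples
#' circ(c(0, 1, 0, 1))
circ <- function(first_row) {
  l <- length(first_row)
  out <- matrix(0, l, l)
  for (r in seq_len(l)) out[r, ] <- first_row[((seq_len(l) - r) %% l) + 1L]
  out
}

#' Build a block-circulant matrix from component blocks
#'
#' `bcirc(A_1, ..., A_m)` arranges m equally-sized square blocks in
#' circulant block pattern: block row r+1 is block row r shifted right by
#' one block.
#'
#' @param ... Square matrices of one common size, or a single list of
#'   them.
#' @return An `mn x mn` matrix.
#' @export
#' @examples
#' bcirc(circ(c(0, 1)), circ(c(1, 1)))  # the 4-neuron command circuit
bcirc <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1 && is.list(blocks[[1]]) && !is.matrix(blocks[[1]])) {
    blocks <- blocks[[1]]
  }
  m <- length(blocks)
  n <- nrow(blocks[[1]])
  stopifnot(all(vapply(blocks, function(b) nrow(b) == n && ncol(b) == n, logical(1))))
  out <- matrix(0, m * n, m * n)
  for (r in seq_len(m)) {
    for (cc in seq_len(m)) {
      out[(r - 1) * n + seq_len(n), (cc - 1) * n + seq_len(n)] <-
        blocks[[((cc - r) %% m) + 1L]]
    }
  }
  out
}

is_circulant_matrix <- function(A) {
  l <- nrow(A)
  all(A == circ(A[1, ]))
}

#' Detect an exact circulant ordering of a block
#'
#' Searches for a node ordering under which the submatrix is exactly
#' circulant. For blocks of size up to `exhaustive_max` all cyclic
#' arrangements are tried (first label fixed); for larger blocks the
#' block's automorphism group is searched for a full-length cycle acting
#' regularly, whose powers define the ordering.
#'
#' @param sub Square numeric matrix (a block of an adjacency matrix).
#' @param labels Optional labels for the rows/columns (defaults to
#'   dimnames or positional names).
#' @param exhaustive_max Largest size for the exhaustive ordering search.
#' @return A `circulant_profile` (fields `first_row`, `length`,
#'   `ordering`, `orderings` for every realizing arrangement found,
#'   `filter_class`, `deviation = 0`), or `NULL` when no ordering is
#'   circulant.
#' @export
detect_circulant <- function(sub, labels = NULL, exhaustive_max = 8) {
  sub <- as.matrix(sub)
  if (nrow(sub) != ncol(sub)) stop("block must be square")
  l <- nrow(sub)
  if (is.null(labels)) labels <- rownames(sub)
  if (is.null(labels)) labels <- paste0("b", seq_len(l))
  if (l == 1) {
    return(new_circulant_profile(sub[1, 1], labels, list(labels), 0))
  }
  hits <- list()
  if (l <= exhaustive_max) {
    for (rest in perms_of(seq_len(l)[-1])) {
      ord <- c(1L, rest)
      if (is_circulant_matrix(sub[ord, ord, drop = FALSE])) {
        hits[[length(hits) + 1L]] <- ord
      }
    }
  } else {
    g <- automorphism_group(circuit_from_block(sub, labels))
    for (p in g$elements) {
      cy <- perm_cycles(p)
      if (length(cy) == 1 && length(cy[[1]]) == l) {
        ord <- match(cy[[1]], labels)
        if (is_circulant_matrix(sub[ord, ord, drop = FALSE])) {
          hits[[length(hits) + 1L]] <- ord
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  orderings <- lapply(hits, function(o) labels[o])
  first <- sub[hits[[1]], hits[[1]], drop = FALSE][1, ]
  new_circulant_profile(first, labels[hits[[1]]], orderings, 0)
}

# all permutations of a vector (small n)
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# wrap a block as a standalone circuit for automorphism search
circuit_from_block <- function(sub, labels) {
  sym <- isTRUE(all.equal(sub, t(sub)))
  circuit(sub, directed = !sym, link_type = "generic", labels = labels)
}

new_circulant_profile <- function(first_row, ordering, orderings, deviation,
                                  heuristic = FALSE) {
  structure(
    list(
      first_row = as.numeric(first_row),
      length = length(first_row),
      ordering = ordering,
      orderings = orderings,
      filter_class = filter_class_of(first_row),
      deviation = deviation,
      heuristic = heuristic
    ),
    class = "circulant_profile"
  )
}

filter_class_of <- function(first_row) {
  fr <- as.numeric(first_row)
  if (all(fr == 0)) return("zero")
  if (identical(fr, c(0, 1))) return("H")
  if (identical(fr, c(1, 1))) return("L")
  if (identical(fr, c(0, 1, 0, 1))) return("F")
  "other"
}

#' @export
print.circulant_profile <- function(x, ...) {
  cat(sprintf("<circulant_profile> circ(%s), class %s, deviation %.3f%s\n",
              paste(x$first_row, collapse = ", "), x$filter_class, x$deviation,
              if (isTRUE(x$heuristic)) " [heuristic]" else ""))
  cat("  ordering:", paste(x$ordering, collapse = " -> "), "\n")
  invisible(x)
}

#' Nearest pseudocirculant approximation of a block
#'
#' Over candidate orderings (exhaustive with the first label fixed up to
#' `exhaustive_max`, heuristic beyond) and over circulant first rows (per
#' diagonal offset, the integer minimizing the L1 distance), finds the
#' circulant matrix closest to the block. The deviation is the fraction
#' of differing link weight, `||A - C||_1 / 2` (undirected link units)
#' over the larger of the two total weights. Ties prefer the
#' lexicographically smallest first row, then ordering.
#'
#' @inheritParams detect_circulant
#' @return A `circulant_profile` with `deviation >= 0`.
#' @export
nearest_pseudocirculant <- function(sub, labels = NULL, exhaustive_max = 10) {
  sub <- as.matrix(sub)
  if (nrow(sub) != ncol(sub)) stop("block must be square")
  l <- nrow(sub)
  if (is.null(labels)) labels <- rownames(sub)
  if (is.null(labels)) labels <- paste0("b", seq_len(l))
  symmetric <- isTRUE(all.equal(sub, t(sub)))
  heuristic <- l > exhaustive_max
  cand_orders <- if (!heuristic) {
    lapply(perms_of(seq_len(l)[-1]), function(rest) c(1L, rest))
  } else {
    # heuristic: order by a greedy heavy-link cycle
    W <- sub + t(sub)
    list(greedy_cycle(max(W) - W))
  }
  if (l == 1) cand_orders <- list(1L)
  best <- NULL
  for (ord in cand_orders) {
    B <- sub[ord, ord, drop = FALSE]
    first <- vapply(seq_len(l), function(d) {
      diag_vals <- B[cbind(seq_len(l), ((seq_len(l) + d - 2) %% l) + 1L)]
      round(stats::median(diag_vals))  # integer L1 minimizer; .5 rounds down
    }, numeric(1))
    if (symmetric) {
      # enforce a symmetric target so the approximant is a valid
      # undirected block: average mirrored offsets
      for (d in seq_len(l)) {
        dd <- ((l - (d - 1)) %% l) + 1L
        v <- floor((first[d] + first[dd]) / 2)
        first[d] <- first[dd] <- v
      }
    }
    first[1] <- 0  # diagonal stays empty (no self-links)
    C <- circ(first)
    dist <- sum(abs(B - C))
    denom <- max(sum(B), sum(C), 1)
    dev <- dist / denom
    key <- list(dev = dev, first = first, ord = ord)
    if (is.null(best) || dev < best$dev ||
        (dev == best$dev && lex_less(first, best$first))) {
      best <- key
    }
  }
  new_circulant_profile(best$first, labels[best$ord],
                        list(labels[best$ord]), best$dev,
                        heuristic = heuristic)
}

lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' Detect block-circulant structure over a block system
#'
#' Given a circuit and an ordered list of equally-sized blocks (label
#' vectors, e.g. from [minimal_blocks()]), checks whether the induced
#' matrix, read block-wise, satisfies the circulant shift property over
#' some cyclic arrangement of the blocks (exhaustive over block orders
#' for up to `max_blocks` blocks). Component blocks are returned with
#' their own circulant profiles when they admit one (the nested
#' hierarchy).
#'
#' @param x A [circuit()].
#' @param blocks List of character vectors (equal sizes, disjoint), with
#'   within-block node order taken as given.
#' @param max_blocks Exhaustive search guard on the number of blocks.
#' @param search_within Also search within-block node orderings (the
#'   circulant-realizing orderings of each block) when the given orders
#'   fail the shift property.
#' @return A `block_circulant_profile` (fields `components` — the
#'   matrices A_1..A_m — `block_order`, `m`, `n`,
#'   `component_profiles`), or `NULL` if no arrangement works.
#' @export
detect_block_circulant <- function(x, blocks, max_blocks = 4,
                                   search_within = FALSE) {
  stopifnot(inherits(x, "circuit"))
  sizes <- vapply(blocks, length, integer(1))
  if (length(unique(sizes)) != 1) stop("blocks must have equal sizes")
  m <- length(blocks)
  n <- sizes[1]
  if (m > max_blocks) stop("too many blocks for exhaustive arrangement search")
  hit <- bcirc_scan(x$A, blocks)
  if (!is.null(hit) || !search_within) return(hit)
  # retry over circulant-realizing orderings of each block
  opts <- lapply(blocks, function(b) {
    pr <- detect_circulant(x$A[b, b, drop = FALSE], labels = b)
    if (is.null(pr)) list(b) else utils::head(pr$orderings, 8L)
  })
  grid <- expand_orderings(opts)
  for (combo in grid) {
    hit <- bcirc_scan(x$A, combo)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# all combinations of per-block ordering options (bounded upstream)
expand_orderings <- function(opts) {
  combos <- list(list())
  for (o in opts) {
    combos <- unlist(lapply(combos, function(cmb) {
      lapply(o, function(ord) c(cmb, list(ord)))
    }), recursive = FALSE)
  }
  combos
}

# core scan over cyclic block arrangements at fixed within-block orders
bcirc_scan <- function(A, blocks) {
  m <- length(blocks)
  n <- length(blocks[[1]])
  arrangements <- if (m == 1) list(1L) else {
    lapply(perms_of(seq_len(m)[-1]), function(rest) c(1L, rest))
  }
  for (arr in arrangements) {
    labs <- unlist(blocks[arr])
    big <- A[labs, labs, drop = FALSE]
    comp <- lapply(seq_len(m), function(j) {
      big[seq_len(n), (j - 1) * n + seq_len(n), drop = FALSE]
    })
    if (all(big == bcirc(comp))) {
      profiles <- lapply(seq_len(m), function(j) {
        detect_circulant(comp[[j]], labels = blocks[[arr[j]]])
      })
      return(structure(
        list(components = comp, block_order = blocks[arr], m = m, n = n,
             component_profiles = profiles),
        class = "block_circulant_profile"
      ))
    }
  }
  NULL
}

#' @export
print.block_circulant_profile <- function(x, ...) {
  cat(sprintf("<block_circulant_profile> bcirc of %d block(s) of order %d\n",
              x$m, x$n))
  for (j in seq_len(x$m)) {
    pr <- x$component_profiles[[j]]
    cat(sprintf("  A_%d: %s\n", j,
                if (is.null(pr)) "not circulant"
                else sprintf("circ(%s) class %s",
                             paste(pr$first_row, collapse = ", "),
                             pr$filter_class)))
  }
  invisible(x)
}

#' Eigen-decomposition of an exact circulant block
#'
#' Eigenvalues are the discrete Fourier transform of the first row;
#' eigenvectors are the Fourier modes, returned as a real orthonormal
#' basis for real symmetric first rows (cosine/sine pairs), each with its
#' first nonzero component positive.
#'
#' @param profile A `circulant_profile` with `deviation == 0`, or a bare
#'   first-row numeric vector.
#' @return A `circulant_eigen` object: `values` (in Fourier-mode order),
#'   `vectors` (columns, unit norm), `first_row`.
#' @export
circulant_eigen <- function(profile) {
  if (inherits(profile, "circulant_profile")) {
    if (profile$deviation != 0) {
      stop("eigen-analysis requires an exact circulant (deviation 0); ",
           "idealize the circuit first")
    }
    fr <- profile$first_row
  } else {
    fr <- as.numeric(profile)
  }
  l <- length(fr)
  lam <- stats::fft(fr)
  symmetric_row <- isTRUE(all.equal(fr[-1], rev(fr[-1])))
  j <- 0:(l - 1)
  if (!symmetric_row) {
    # complex spectrum: eigenvectors are the raw Fourier modes, in
    # conjugate pairs
    vectors <- outer(j, j, function(a, b) exp(-2i * pi * a * b / l)) / sqrt(l)
    return(structure(list(values = lam, vectors = vectors, first_row = fr),
                     class = "circulant_eigen"))
  }
  lam <- Re(lam)
  vectors <- matrix(0, l, l)
  values <- numeric(l)
  k_used <- 1L
  for (k in j) {
    if (k_used > l) break
    if (k == 0 || (l %% 2 == 0 && k == l / 2)) {
      v <- cos(2 * pi * k * j / l)
      vectors[, k_used] <- v / sqrt(sum(v^2))
      values[k_used] <- lam[k + 1]
      k_used <- k_used + 1L
    } else if (k < l - k) {
      vc <- cos(2 * pi * k * j / l)
      vs <- sin(2 * pi * k * j / l)
      vectors[, k_used] <- vc / sqrt(sum(vc^2))
      values[k_used] <- lam[k + 1]
      vectors[, k_used + 1L] <- vs / sqrt(sum(vs^2))
      values[k_used + 1L] <- lam[l - k + 1]
      k_used <- k_used + 2L
    }
  }
  # deterministic sign: first nonzero component positive
  for (cc in seq_len(l)) {
    v <- vectors[, cc]
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) vectors[, cc] <- -v
  }
  structure(list(values = values, vectors = vectors, first_row = fr),
            class = "circulant_eigen")
}

#' @export
print.circulant_eigen <- function(x, ...) {
  cat("<circulant_eigen> circ(", paste(x$first_row, collapse = ", "), ")\n")
  cat("  eigenvalues:", paste(format(x$values, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Classify a circulant block as a signal-processing filter
#'
#' Exact matches to the catalogue: `circ(0,1)` is the high-pass filter H,
#' `circ(1,1)` the low-pass filter L, `circ(0,1,0,1)` the subsampling
#' kernel F, the all-zero row is `zero`; anything else is `other`, with
#' the DFT magnitude spectrum attached as its frequency response.
#'
#' @param profile A `circulant_profile` or bare first-row vector.
#' @return A list with `class` and, for `other`, `response` (the `|DFT|`
#'   magnitudes).
#' @export
classify_filter <- function(profile) {
  fr <- if (inherits(profile, "circulant_profile")) profile$first_row
        else as.numeric(profile)
  cls <- filter_class_of(fr)
  out <- list(class = cls)
  if (cls == "other") out$response <- Mod(stats::fft(fr))
  out
}
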