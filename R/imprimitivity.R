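#' Orbits of a permutation group
#'
#' Connected components of the union of the generator (or element)
#' mappings: two labels are in one orbit when some group element maps one
#' to the other.
#'
#' @param g A [perm_group()] (generators suffice; materialization not
#'   required).
#' @return A list of character vectors partitioning the label set, each
#'   sorted, ordered by first label position.
#' @export
orbits <- function(g) {
  stopifnot(inherits(g, "perm_group"))
  perms <- if (!is.null(g$elements)) g$elements else g$generators
  n <- length(g$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (p in perms) {
    img <- unclass(p)
    for (i in seq_len(n)) {
      ri <- find(i); rj <- find(img[i])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) sort(g$labels[roots == r]))
  first_pos <- vapply(out, function(s) min(match(s, g$labels)), integer(1))
  out[order(first_pos)]
}

# union-find block refinement: minimal block system whose block contains
# the seed pair, for a transitive action on `orbit`
block_refine <- function(perms, labels, orbit, seed_pair) {
  ix <- match(orbit, labels)
  pos <- integer(length(labels))
  pos[ix] <- seq_along(ix)
  m <- length(ix)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    ra != rb
  }
  union2(pos[match(seed_pair[1], labels)], pos[match(seed_pair[2], labels)])
  repeat {
    changed <- FALSE
    for (p in perms) {
      img <- unclass(p)
      for (i in seq_len(m)) {
        r <- find(i)
        if (r != i) {
          # i and its class representative must stay together under p
          a <- pos[img[ix[i]]]
          b <- pos[img[ix[r]]]
          if (union2(a, b)) changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  roots <- vapply(seq_len(m), find, integer(1))
  blocks <- lapply(unique(roots), function(r) sort(orbit[roots == r]))
  first_pos <- vapply(blocks, function(b) min(match(b, orbit)), integer(1))
  blocks[order(first_pos)]
}

#' Minimal block system containing a seed pair
#'
#' For a group acting transitively on an orbit, computes the finest
#' partition into blocks of imprimitivity whose block contains both seed
#' labels: the seed labels are merged and images under the generators are
#' propagated until every group element maps each block onto itself or
#' onto a disjoint block.
#'
#' @param g A [perm_group()].
#' @param orbit Character vector, an orbit of `g` (see [orbits()]).
#' @param seed_pair Two distinct labels inside `orbit`.
#' @return A `block_system` with fields `blocks` (list of sorted label
#'   sets), `orbit`, `trivial` (singletons or the whole orbit).
#' @export
minimal_blocks <- function(g, orbit, seed_pair) {
  stopifnot(inherits(g, "perm_group"), length(seed_pair) == 2)
  check_transitive(g, orbit)
  if (!all(seed_pair %in% orbit)) stop("seed pair must lie inside the orbit")
  perms <- g$generators  # invariance under generators implies the group
  blocks <- block_refine(perms, g$labels, orbit, seed_pair)
  new_block_system(blocks, orbit)
}

new_block_system <- function(blocks, orbit) {
  sizes <- vapply(blocks, length, integer(1))
  structure(
    list(blocks = blocks, orbit = orbit,
         trivial = length(blocks) == 1 || all(sizes == 1)),
    class = "block_system"
  )
}

#' @export
print.block_system <- function(x, ...) {
  cat(sprintf("<block_system> %d block(s) of size %d on orbit of %d%s\n",
              length(x$blocks), length(x$blocks[[1]]), length(x$orbit),
              if (x$trivial) " [trivial]" else ""))
  for (b in x$blocks) cat("  {", paste(b, collapse = ", "), "}\n")
  invisible(x)
}

check_transitive <- function(g, orbit) {
  orbs <- orbits(g)
  hit <- Filter(function(o) any(orbit %in% o), orbs)
  if (length(hit) != 1 || !setequal(hit[[1]], orbit)) {
    stop("group is not transitive on the given label set; ",
         "analyze each orbit separately")
  }
  invisible(TRUE)
}

#' All minimal block systems on an orbit
#'
#' Runs [minimal_blocks()] for every seed pair (first orbit label against
#' each other label — every block through the first point arises this
#' way) and deduplicates. Trivial systems (all singletons, or one block
#' covering the orbit) are reported separately.
#'
#' @inheritParams minimal_blocks
#' @return A list with `nontrivial` (list of `block_system`s) and
#'   `trivial` (list of `block_system`s).
#' @export
block_systems <- function(g, orbit) {
  check_transitive(g, orbit)
  a <- orbit[1]
  seen <- character(0)
  nontrivial <- list()
  trivial <- list()
  for (b in orbit[-1]) {
    bs <- minimal_blocks(g, orbit, c(a, b))
    key <- paste(vapply(bs$blocks, paste, character(1), collapse = ","),
                 collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (bs$trivial) trivial[[length(trivial) + 1L]] <- bs
    else nontrivial[[length(nontrivial) + 1L]] <- bs
  }
  # the all-singletons system always exists; include it among trivials
  singles <- new_block_system(as.list(orbit), orbit)
  trivial[[length(trivial) + 1L]] <- singles
  list(nontrivial = nontrivial, trivial = trivial)
}

#' Primitivity test
#'
#' A transitive action is primitive when it admits no nontrivial block
#' system.
#'
#' @inheritParams minimal_blocks
#' @return Logical.
#' @export
is_primitive <- function(g, orbit) {
  if (length(orbit) <= 2) {
    check_transitive(g, orbit)
    return(TRUE)  # no nontrivial divisor of the orbit size
  }
  length(block_systems(g, orbit)$nontrivial) == 0
}

#' Verify the block property of a system under a group
#'
#' Every group element must map each block onto itself or onto a disjoint
#' block. Used in tests and reports; exhaustive over elements.
#'
#' @param g A materialized [perm_group()].
#' @param bs A `block_system`.
#' @return Logical.
#' @export
verify_blocks <- function(g, bs) {
  stopifnot(inherits(bs, "block_system"))
  perms <- if (!is.null(g$elements)) g$elements else g$generators
  for (p in perms) {
    img <- unclass(p)
    for (b in bs$blocks) {
      bimg <- g$labels[img[match(b, g$labels)]]
      inter <- intersect(bimg, b)
      if (length(inter) != 0 && !setequal(bimg, b)) return(FALSE)
    }
  }
  TRUE
}
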