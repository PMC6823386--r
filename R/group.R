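#' Finite permutation group
#'
#' A `perm_group` holds a finite group of node permutations acting on a
#' fixed label set: a generating set and, when materialized, the full
#' element list. Construct one from generators with [closure()] or
#' directly from a known element set.
#'
#' @param generators List of [node_perm()]s.
#' @param elements Optional list of all elements (must contain the
#'   identity and be closed; not re-verified here — use [closure()] when
#'   in doubt).
#' @param labels Labels acted upon; taken from the permutations if omitted.
#' @return A `perm_group` with fields `generators`, `elements`, `order`,
#'   `labels`.
#' @export
perm_group <- function(generators = NULL, elements = NULL, labels = NULL) {
  if (is.null(generators) && is.null(elements)) stop("need generators or elements")
  probe <- if (!is.null(elements) && length(elements)) elements[[1]] else generators[[1]]
  if (is.null(labels)) labels <- attr(probe, "labels")
  if (is.null(generators)) {
    generators <- minimal_generators(elements, labels)
  }
  structure(
    list(
      generators = generators,
      elements = elements,
      order = if (is.null(elements)) NA_integer_ else length(elements),
      labels = labels
    ),
    class = "perm_group"
  )
}

#' @export
print.perm_group <- function(x, ...) {
  cat(sprintf("<perm_group> order %s on %d labels, %d generator(s)\n",
              ifelse(is.na(x$order), "?", x$order), length(x$labels),
              length(x$generators)))
  for (g in utils::head(x$generators, 6)) cat("  ", format(g), "\n")
  invisible(x)
}

#' Group order
#' @param g A [perm_group()], materialized.
#' @return Integer order.
#' @export
group_order <- function(g) {
  stopifnot(inherits(g, "perm_group"))
  if (is.na(g$order)) stop("group not materialized; call closure() first")
  g$order
}

#' Close a generating set into a full group
#'
#' Breadth-first products of the generators until no new element appears.
#'
#' @param gens A list of [node_perm()]s on a common label set, or a
#'   `perm_group`.
#' @param cap Maximum order explored before aborting.
#' @return A materialized [perm_group()].
#' @export
closure <- function(gens, cap = 1e6) {
  if (inherits(gens, "perm_group")) gens <- gens$generators
  if (inherits(gens, "node_perm")) gens <- list(gens)
  stopifnot(length(gens) >= 1)
  labels <- attr(gens[[1]], "labels")
  for (g in gens) {
    if (!identical(attr(g, "labels"), labels)) {
      stop("all generators must act on the same label set")
    }
  }
  raw <- closure_raw(lapply(gens, unclass), length(labels), cap)
  elements <- lapply(raw, node_perm, labels = labels)
  perm_group(generators = gens, elements = elements, labels = labels)
}

# BFS closure on raw integer image vectors
closure_raw <- function(gens_raw, n, cap = 1e6) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  id <- seq_len(n)
  assign(paste(id, collapse = ","), TRUE, envir = seen)
  elements <- list(id)
  frontier <- list(id)
  while (length(frontier)) {
    nxt <- list()
    for (e in frontier) {
      for (g in gens_raw) {
        prod <- g[e]
        k <- paste(prod, collapse = ",")
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          elements[[length(elements) + 1L]] <- prod
          nxt[[length(nxt) + 1L]] <- prod
          if (length(elements) > cap) {
            stop("closure cap exceeded: order is at least ", length(elements))
          }
        }
      }
    }
    frontier <- nxt
  }
  elements
}

# small generating set recovered from an element list (greedy: add any
# element not yet generated; each addition at least doubles the subgroup,
# so at most log2(order) closure passes)
minimal_generators <- function(elements, labels) {
  if (length(elements) <= 1) return(list(perm_identity(labels)))
  n <- length(labels)
  target <- length(elements)
  raw <- lapply(elements, unclass)
  keys <- vapply(raw, paste, character(1), collapse = ",")
  supp <- vapply(raw, function(r) sum(r != seq_len(n)), integer(1))
  ord <- order(supp, keys)
  raw <- raw[ord]
  gens_raw <- list()
  have_keys <- paste(seq_len(n), collapse = ",")
  for (e in raw) {
    if (all(e == seq_len(n))) next
    if (paste(e, collapse = ",") %in% have_keys) next
    gens_raw <- c(gens_raw, list(e))
    cl <- closure_raw(gens_raw, n, cap = target + 1L)
    have_keys <- vapply(cl, paste, character(1), collapse = ",")
    if (length(cl) == target) break
  }
  lapply(gens_raw, node_perm, labels = labels)
}

#' Membership test
#' @param g A materialized [perm_group()].
#' @param p A [node_perm()].
#' @return Logical.
#' @export
group_contains <- function(g, p) {
  keys <- vapply(g$elements, perm_key, character(1))
  perm_key(p) %in% keys
}

#' Is H a normal subgroup of G?
#'
#' Checks coset equality `gH = Hg` for every element `g` of the parent
#' group, i.e. that conjugation by any group element maps H onto itself.
#'
#' @param h,g Materialized [perm_group()]s; `h`'s elements must all belong
#'   to `g`.
#' @return Logical.
#' @export
is_normal <- function(h, g) {
  stopifnot(inherits(h, "perm_group"), inherits(g, "perm_group"))
  gk <- sort(vapply(g$elements, perm_key, character(1)))
  hk <- sort(vapply(h$elements, perm_key, character(1)))
  if (!all(hk %in% gk)) stop("h is not a subgroup of g (element not in g)")
  hset <- hk
  for (x in g$elements) {
    xinv <- invert_perm(x)
    conj <- vapply(h$elements, function(e) {
      perm_key(compose_perm(x, compose_perm(e, xinv)))
    }, character(1))
    if (!identical(sort(conj), hset)) return(FALSE)
  }
  TRUE
}

#' Factorize a group into normal subgroups acting on disjoint sectors
#'
#' Splits a materialized permutation group into a direct product of
#' factors, each acting on its own disjoint set of moved labels (its
#' "sector"). Orbits are computed first; two orbit sets are merged when
#' the group's action on their union is not the direct product of its
#' actions on each part (fewer joint restrictions than the product of the
#' marginal counts). Each final sector's factor is the set of group
#' elements supported inside that sector. The factorization is verified:
#' factors must multiply to the group order, be mutually normal, and
#' intersect trivially; `residual = TRUE` flags a failed verification.
#'
#' @param g A materialized [perm_group()].
#' @return A `group_factorization` with `factors` (list of
#'   `list(subgroup, sector, name, order)`), `residual`, and `group`.
#' @export
factorize <- function(g) {
  stopifnot(inherits(g, "perm_group"))
  if (is.na(g$order)) stop("group not materialized; call closure() first")
  orb <- orbits(g)
  orb <- orb[vapply(orb, length, integer(1)) > 1]  # fixed points excluded
  if (!length(orb)) {
    return(structure(list(factors = list(), residual = FALSE, group = g),
                     class = "group_factorization"))
  }
  orb_idx <- lapply(orb, match, table = g$labels)
  k <- length(orb)
  n <- length(g$labels)
  E <- do.call(rbind, lapply(g$elements, unclass))  # element image matrix
  n_restr <- function(cols) {
    nrow(unique(E[, cols, drop = FALSE]))
  }
  marg <- vapply(orb_idx, n_restr, integer(1))
  # link orbits whose joint action is not a direct product
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) {
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        joint <- n_restr(c(orb_idx[[a]], orb_idx[[b]]))
        if (joint < marg[a] * marg[b]) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  sectors <- lapply(unique(roots), function(r) {
    sort(unlist(orb[roots == r]))
  })
  # stable order: by first label position in the circuit
  first_pos <- vapply(sectors, function(s) min(match(s, g$labels)), integer(1))
  sectors <- sectors[order(first_pos)]

  # Verification that G is the direct product of its sector factors:
  # each factor (the elements supported inside one sector) must realize
  # every restriction of G to that sector, and the factor orders must
  # multiply to |G|. Both together imply mutual normality, so the
  # expensive elementwise conjugation check is not repeated here.
  factors <- list()
  residual <- FALSE
  moved_mask <- E != matrix(seq_len(n), nrow(E), n, byrow = TRUE)
  for (sector in sectors) {
    six <- match(sector, g$labels)
    inside_rows <- which(rowSums(moved_mask[, -six, drop = FALSE]) == 0)
    inside <- g$elements[inside_rows]
    sub <- perm_group(elements = inside, labels = g$labels)
    nm <- identify_group(sub)
    if (length(inside_rows) != n_restr(six)) residual <- TRUE
    factors[[length(factors) + 1L]] <-
      list(subgroup = sub, sector = sector, name = nm, order = sub$order)
  }
  prod_order <- prod(vapply(factors, `[[`, numeric(1), "order"))
  if (prod_order != g$order) residual <- TRUE
  structure(list(factors = factors, residual = residual, group = g),
            class = "group_factorization")
}

#' @export
print.group_factorization <- function(x, ...) {
  cat(sprintf("<group_factorization> order %d = %s%s\n",
              x$group$order,
              paste(vapply(x$factors, `[[`, character(1), "name"), collapse = " x "),
              if (x$residual) "  [residual: verification failed]" else ""))
  for (f in x$factors) {
    cat(sprintf("  %-6s order %-4d sector: %s\n", f$name, f$order,
                paste(f$sector, collapse = ", ")))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a factorization into a tibble
#'
#' @param x A `group_factorization`.
#' @param ... Unused.
#' @return A tibble with columns `name`, `order`, `sector_size`, `sector`
#'   (list-column), `generators` (list-column of cycle strings).
#' @export
tidy.group_factorization <- function(x, ...) {
  tibble::tibble(
    name = vapply(x$factors, `[[`, character(1), "name"),
    order = vapply(x$factors, `[[`, numeric(1), "order"),
    sector_size = vapply(x$factors, function(f) length(f$sector), integer(1)),
    sector = lapply(x$factors, `[[`, "sector"),
    generators = lapply(x$factors, function(f) {
      vapply(f$subgroup$generators, format, character(1))
    })
  )
}

#' Name a small permutation group
#'
#' Tags a materialized group as cyclic (`C_n`), dihedral (`D_n`, named by
#' its *order* so the square's symmetry group is `D_8`), symmetric
#' (`S_k` on its k moved points), or `other(order)`. Order-2 groups follow
#' the circuit-analysis convention: a single transposition is `C_2`, an
#' involution moving more than two points is `D_1`.
#'
#' @param h A materialized [perm_group()].
#' @param dihedral_by_order Name dihedral groups by element count
#'   (default; `D_8` has 8 elements) rather than by polygon size.
#' @return A character tag.
#' @export
identify_group <- function(h, dihedral_by_order = TRUE) {
  stopifnot(inherits(h, "perm_group"))
  if (is.na(h$order)) stop("group not materialized; call closure() first")
  n <- h$order
  if (n == 1) return("trivial")
  moved <- unique(unlist(lapply(h$elements, perm_support)))
  if (n == 2) {
    return(if (length(moved) == 2) "C_2" else "D_1")
  }
  ords <- vapply(h$elements, perm_order, numeric(1))
  if (any(ords == n)) return(paste0("C_", n))
  if (n == factorial(length(moved))) return(paste0("S_", length(moved)))
  # dihedral: a cyclic subgroup of index 2 plus an inverting involution
  if (n %% 2 == 0 && any(ords == n / 2)) {
    r <- h$elements[[which(ords == n / 2)[1]]]
    rot <- closure(list(r), cap = n)
    rot_keys <- vapply(rot$elements, perm_key, character(1))
    rinv_key <- perm_key(invert_perm(r))
    for (s in h$elements) {
      if (perm_order(s) == 2 && !perm_key(s) %in% rot_keys) {
        conj <- compose_perm(s, compose_perm(r, invert_perm(s)))
        if (perm_key(conj) == rinv_key) {
          return(if (dihedral_by_order) paste0("D_", n) else paste0("D_", n / 2))
        }
      }
    }
  }
  paste0("other(", n, ")")
}

#' Serialize a factorization to JSON
#'
#' @param x A `group_factorization`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string or `path` invisibly.
#' @export
factorization_json <- function(x, path = NULL) {
  payload <- lapply(x$factors, function(f) {
    list(
      name = f$name,
      order = f$order,
      sector = f$sector,
      generators = vapply(f$subgroup$generators, format, character(1))
    )
  })
  js <- jsonlite::toJSON(list(order = x$group$order, residual = x$residual,
                              factors = payload), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
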