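#' Node permutations
#'
#' A `node_perm` is a bijection on a circuit's label set, stored as an
#' integer image vector (`p[i]` is the index of the image of node `i`)
#' with the labels attached. Permutations compose with [compose_perm()]
#' and invert with [invert_perm()].
#'
#' @param mapping Named character vector (`names` are moved labels, values
#'   their images), or an integer image vector over all of `labels`.
#' @param labels Character vector of all labels acted upon.
#' @return A `node_perm` object.
#' @export
#' @examples
#' node_perm(c(AVBL = "AVBR", AVBR = "AVBL"), labels = c("AVBL", "AVBR", "RIBL"))
node_perm <- function(mapping, labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.numeric(mapping)) {
    img <- as.integer(mapping)
    if (length(img) != n) stop("image vector must cover all labels")
  } else {
    img <- seq_len(n)
    from <- match(names(mapping), labels)
    to <- match(unname(mapping), labels)
    if (anyNA(from) || anyNA(to)) {
      stop("permutation mentions a label not in the circuit: ",
           paste(c(names(mapping), mapping)[is.na(c(from, to))][1]))
    }
    img[from] <- to
  }
  if (!identical(sort(img), seq_len(n))) stop("mapping is not a bijection on the labels")
  structure(img, labels = labels, class = "node_perm")
}

#' Permutation from cycle notation
#'
#' @param cycles A list of character vectors; each vector `c(a, b, c)` maps
#'   `a -> b -> c -> a`. Cycles must be disjoint.
#' @param labels All labels acted upon.
#' @return A `node_perm`.
#' @export
perm_from_cycles <- function(cycles, labels) {
  if (is.character(cycles)) cycles <- list(cycles)
  moved <- unlist(cycles)
  if (anyDuplicated(moved)) stop("cycles must be disjoint")
  mapping <- character(0)
  for (cy in cycles) {
    if (length(cy) < 2) next
    mapping[cy] <- cy[c(seq_along(cy)[-1], 1L)]
  }
  node_perm(mapping, labels)
}

#' Identity permutation on a label set
#' @param labels Character vector of labels.
#' @return A `node_perm`.
#' @export
perm_identity <- function(labels) {
  node_perm(seq_along(labels), labels)
}

#' Compose two permutations
#'
#' `compose_perm(p, q)` applies `q` first, then `p` (the usual function
#' composition `p(q(.))`).
#'
#' @param p,q `node_perm` objects on the same labels.
#' @return A `node_perm`.
#' @export
compose_perm <- function(p, q) {
  stopifnot(identical(attr(p, "labels"), attr(q, "labels")))
  node_perm(unclass(p)[unclass(q)], attr(p, "labels"))
}

#' Invert a permutation
#' @param p A `node_perm`.
#' @return A `node_perm`.
#' @export
invert_perm <- function(p) {
  node_perm(order(unclass(p)), attr(p, "labels"))
}

#' Labels moved by a permutation
#' @param p A `node_perm`.
#' @return Character vector of labels with `p(i) != i` (empty for the
#'   identity).
#' @export
perm_support <- function(p) {
  attr(p, "labels")[unclass(p) != seq_along(p)]
}

#' Cycle decomposition of a permutation
#' @param p A `node_perm`.
#' @return A list of character vectors, the nontrivial cycles (fixed points
#'   omitted), each cycle starting at its lexicographically smallest label,
#'   cycles sorted by first label.
#' @export
perm_cycles <- function(p) {
  img <- unclass(p)
  labels <- attr(p, "labels")
  seen <- logical(length(img))
  out <- list()
  for (i in seq_along(img)) {
    if (seen[i] || img[i] == i) next
    cy <- i
    j <- img[i]
    seen[i] <- TRUE
    while (j != i) {
      seen[j] <- TRUE
      cy <- c(cy, j)
      j <- img[j]
    }
    lab <- labels[cy]
    k <- which(lab == min(lab))[1]
    out[[length(out) + 1L]] <- lab[c(seq_along(lab), seq_along(lab))[k:(k + length(lab) - 1L)]]
  }
  if (length(out)) out[order(vapply(out, `[`, character(1), 1L))] else out
}

#' @export
print.node_perm <- function(x, ...) {
  cy <- perm_cycles(x)
  if (!length(cy)) {
    cat("<node_perm> identity on", length(x), "labels\n")
  } else {
    cat("<node_perm>", paste(vapply(cy, function(c) {
      paste0("(", paste(c, collapse = " "), ")")
    }, character(1)), collapse = ""), "\n")
  }
  invisible(x)
}

#' @export
format.node_perm <- function(x, ...) {
  cy <- perm_cycles(x)
  if (!length(cy)) return("()")
  paste(vapply(cy, function(c) paste0("(", paste(c, collapse = " "), ")"),
               character(1)), collapse = "")
}

# order of a permutation (lcm of cycle lengths)
perm_order <- function(p) {
  cy <- perm_cycles(p)
  if (!length(cy)) return(1L)
  lens <- vapply(cy, length, integer(1))
  Reduce(function(a, b) a * b / gcd2(a, b), lens, accumulate = FALSE)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

perm_key <- function(p) paste(unclass(p), collapse = ",")
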