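#' Weighted neural circuit
#'
#' A `circuit` bundles a labeled, nonnegative-integer weighted adjacency
#' matrix with its directedness and link type. Gap-junction circuits are
#' undirected (the matrix is symmetric); chemical-synapse circuits are
#' directed. Entry `A[i, j]` counts the number of connections from neuron
#' `i` to neuron `j`; self-connections are out of scope and the diagonal
#' must be zero.
#'
#' @param A Square numeric matrix of nonnegative integers. Row/column names,
#'   if present, become the node labels; otherwise `labels` is required.
#' @param directed Logical; `FALSE` for gap junctions, `TRUE` for chemical
#'   synapses.
#' @param link_type One of `"gap"`, `"chemical"`, `"generic"`.
#' @param labels Optional character vector of node labels overriding
#'   dimnames.
#'
#' @return An object of class `circuit` with fields `labels`, `A`,
#'   `directed`, `link_type`.
#' @export
#' @examples
#' A <- rbind(c(0, 1), c(1, 0))
#' circuit(A, directed = FALSE, labels = c("AVBL", "AVBR"))
circuit <- function(A, directed = FALSE, link_type = if (directed) "chemical" else "gap",
                    labels = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (is.null(labels)) labels <- rownames(A)
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(A)))
  labels <- as.character(labels)
  if (length(labels) != nrow(A)) stop("number of labels must equal matrix dimension")
  if (anyDuplicated(labels)) stop("node labels must be unique")
  if (any(A < 0) || any(A != round(A))) stop("weights must be nonnegative integers")
  if (any(diag(A) != 0)) stop("diagonal must be zero (no self-connections)")
  if (!directed && !isTRUE(all.equal(A, t(A)))) {
    stop("undirected circuit requires a symmetric adjacency matrix")
  }
  link_type <- match.arg(link_type, c("gap", "chemical", "generic"))
  storage.mode(A) <- "double"
  dimnames(A) <- list(labels, labels)
  structure(
    list(labels = labels, A = A, directed = directed, link_type = link_type),
    class = "circuit"
  )
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf(
    "<circuit> %d neurons, %s %s links, total weight M = %d\n",
    length(x$labels),
    if (x$directed) "directed" else "undirected",
    x$link_type,
    total_weight(x)
  ))
  cat("neurons:", paste(utils::head(x$labels, 12), collapse = ", "),
      if (length(x$labels) > 12) "..." else "", "\n")
  invisible(x)
}

#' Read a circuit from a TSV edge list
#'
#' The file must have columns `source`, `target`, `weight`, `type`
#' (tab-separated, with header). Duplicate rows for the same ordered pair
#' are summed. For undirected circuits the matrix is symmetrized; listing
#' both orientations of an undirected link with *different* weights is
#' rejected as inconsistent. Node order is first appearance in the file.
#'
#' @param path Path to a TSV file.
#' @param directed Logical or `NULL`. When `NULL`, directedness is inferred
#'   from the `type` column (`gap` is undirected, `chemical` directed).
#' @return A [circuit()].
#' @export
read_circuit <- function(path, directed = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_circuit(df, directed = directed)
}

#' Build a circuit from an edge-list data frame
#'
#' @param edges Data frame with columns `source`, `target`, `weight` and
#'   optionally `type`.
#' @inheritParams read_circuit
#' @return A [circuit()].
#' @export
as_circuit <- function(edges, directed = NULL) {
  need <- c("source", "target", "weight")
  if (!all(need %in% names(edges))) {
    stop("edge list needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(edges) == 0) stop("edge list is empty: a circuit needs at least one link")
  bad <- which(is.na(edges$source) | is.na(edges$target) | !nzchar(edges$source) |
                 !nzchar(edges$target) | is.na(edges$weight))
  if (length(bad)) stop("malformed edge row at line ", bad[1] + 1L)
  w <- edges$weight
  if (any(w <= 0) || any(w != round(w))) {
    stop("validation error: weights must be positive integers (row ",
         which(w <= 0 | w != round(w))[1], ")")
  }
  type <- if ("type" %in% names(edges)) as.character(edges$type) else rep("generic", nrow(edges))
  link_type <- unique(type)
  if (length(link_type) > 1) stop("a circuit carries a single link type, got: ",
                                  paste(link_type, collapse = ", "))
  if (is.null(directed)) {
    directed <- switch(link_type, gap = FALSE, chemical = TRUE,
                       stop("cannot infer directedness for link type '", link_type,
                            "'; pass `directed`"))
  }
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  if (any(src == tgt)) stop("self-connection declared for ", src[src == tgt][1])
  labels <- unique(c(rbind(src, tgt)))  # first-appearance order
  n <- length(labels)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  for (k in seq_along(src)) A[src[k], tgt[k]] <- A[src[k], tgt[k]] + w[k]
  if (!directed) {
    # both orientations may be listed; they must agree where both appear
    both <- A > 0 & t(A) > 0
    if (any(A[both] != t(A)[both])) {
      stop("validation error: asymmetric duplicate declaration for undirected input")
    }
    A <- pmax(A, t(A))
  }
  circuit(A, directed = directed,
          link_type = if (link_type %in% c("gap", "chemical")) link_type else "generic")
}

#' Write a circuit as a TSV edge list
#'
#' Inverse of [read_circuit()]: undirected links are written once (upper
#' triangle, in node order), so read -> write -> read round-trips exactly.
#'
#' @param x A [circuit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(x, path) {
  stopifnot(inherits(x, "circuit"))
  df <- circuit_edges(x)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Tidy edge list of a circuit
#'
#' @param x A [circuit()].
#' @return A tibble with columns `source`, `target`, `weight`, `type`;
#'   undirected links appear once.
#' @export
circuit_edges <- function(x) {
  stopifnot(inherits(x, "circuit"))
  A <- x$A
  idx <- which(A > 0, arr.ind = TRUE)
  if (!x$directed) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  # order rows so that reading the file re-creates the label order: sort
  # by the later-appearing endpoint, then the earlier one (first
  # appearance in the written file then replays the node order)
  lo <- pmin(idx[, 1], idx[, 2])
  hi <- pmax(idx[, 1], idx[, 2])
  ord <- order(hi, lo, idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  tibble::tibble(
    source = x$labels[idx[, 1]],
    target = x$labels[idx[, 2]],
    weight = as.integer(A[idx]),
    type = x$link_type
  )
}

#' Total link weight of a circuit
#'
#' The total number of links counted with their weights: the sum of the
#' adjacency matrix over unordered pairs for undirected circuits (half the
#' full matrix sum) and over ordered pairs for directed ones. This is the
#' denominator M of the uncertainty constant epsilon.
#'
#' @param x A [circuit()].
#' @return A nonnegative integer.
#' @export
total_weight <- function(x) {
  stopifnot(inherits(x, "circuit"))
  s <- sum(x$A)
  as.integer(if (x$directed) s else s / 2)
}

#' Induced sub-circuit
#'
#' Restricts a circuit to a subset of its neurons, keeping only the links
#' among them, in the order given.
#'
#' @param x A [circuit()].
#' @param labels Character vector, a subset of `x$labels`.
#' @return A [circuit()] on `labels`.
#' @export
subcircuit <- function(x, labels) {
  stopifnot(inherits(x, "circuit"))
  unknown <- setdiff(labels, x$labels)
  if (length(unknown)) stop("unknown label: ", unknown[1])
  circuit(x$A[labels, labels, drop = FALSE], directed = x$directed,
          link_type = x$link_type, labels = labels)
}

#' Export a circuit to GraphML (via igraph) for visualization
#'
#' @param x A [circuit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circuit_graphml <- function(x, path) {
  g <- circuit_igraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# igraph view of a circuit (weighted; used by baselines and export)
circuit_igraph <- function(x, force_undirected = FALSE) {
  A <- x$A
  if (force_undirected && x$directed) A <- A + t(A)
  mode <- if (x$directed && !force_undirected) "directed" else "undirected"
  igraph::graph_from_adjacency_matrix(A, mode = mode, weighted = TRUE)
}

#' Adjacency heatmap of a circuit
#'
#' @param object A [circuit()].
#' @param ... Unused.
#' @return A ggplot object showing the weighted adjacency matrix in node
#'   order (rows top to bottom).
#' @export
autoplot.circuit <- function(object, ...) {
  df <- tidyr::expand_grid(
    source = factor(object$labels, levels = object$labels),
    target = factor(object$labels, levels = object$labels)
  )
  df$weight <- as.vector(t(object$A))  # row-major: source varies slowest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$weight)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10") +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
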