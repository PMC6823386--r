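#' Specification for a planted-symmetry circuit
#'
#' Describes a circuit assembled from disjoint neuron sectors, each
#' carrying a planted permutation group, wired to a set of hub ("command")
#' nodes. Sector types:
#'
#' * `"S_n"` — n nodes wired identically (to hubs only, no internal
#'   links): the full symmetric group.
#' * `"C_n"` — n nodes on a directed/undirected ring (`internal` defaults
#'   to the unit cycle `circ(0, 1, 0, ..., 0, 1)` for n > 2, a single
#'   link for n = 2): cyclic rotations.
#' * `"D_1"` — two equal blocks with a planted involution pairing them
#'   elementwise; `internal` is the full sector matrix (default: two
#'   `circ(0,1,0,1)` 4-cycles with weight-2 cross links pairing the
#'   blocks antidiagonally).
#'
#' `hub_weights` gives each sector node's link weight to every hub label
#' (a single number, one per hub, or a `label x hub` matrix). Weights
#' must be constant on the orbits of the planted generators, otherwise
#' the plant is rejected.
#'
#' @param sectors List of sector descriptions
#'   (`list(type =, labels =, hub_weights =, internal =, blocks =)`).
#' @param hub_labels Character vector of hub node labels.
#' @param hub_internal Square matrix of links among hubs (default none).
#' @param hub_groups Optional list of planted groups on the hubs, each
#'   `list(type = "C_2", labels = c(a, b))`.
#' @param perturb_fraction Fraction of link units to perturb in `[0, 1)`.
#' @param seed Seed for the perturbation (mandatory when
#'   `perturb_fraction > 0`).
#' @return A `plant_spec`.
#' @export
plant_spec <- function(sectors, hub_labels = character(0), hub_internal = NULL,
                       hub_groups = list(), perturb_fraction = 0, seed = NULL) {
  all_labels <- c(hub_labels, unlist(lapply(sectors, sector_labels)))
  if (anyDuplicated(all_labels)) {
    stop("sectors (and hubs) must be disjoint; duplicated label: ",
         all_labels[duplicated(all_labels)][1])
  }
  if (perturb_fraction < 0 || perturb_fraction >= 1) {
    stop("perturb_fraction must be in [0, 1)")
  }
  if (perturb_fraction > 0 && is.null(seed)) {
    stop("a seed is mandatory when perturbing")
  }
  structure(list(sectors = sectors, hub_labels = hub_labels,
                 hub_internal = hub_internal, hub_groups = hub_groups,
                 perturb_fraction = perturb_fraction, seed = seed),
            class = "plant_spec")
}

sector_labels <- function(s) {
  if (!is.null(s$labels)) s$labels else unlist(s$blocks)
}

# default internal matrix for a sector description
sector_internal <- function(s) {
  labs <- sector_labels(s)
  k <- length(labs)
  if (!is.null(s$internal)) {
    m <- as.matrix(s$internal)
    stopifnot(nrow(m) == k, ncol(m) == k)
    return(m)
  }
  if (grepl("^S", s$type)) return(matrix(0, k, k))
  if (grepl("^C", s$type)) {
    if (k == 2) return(circ(c(0, 1)))
    fr <- numeric(k); fr[2] <- 1; fr[k] <- 1
    return(circ(fr))
  }
  if (s$type == "D_1") {
    stopifnot(length(s$blocks) == 2, length(s$blocks[[1]]) == length(s$blocks[[2]]))
    n <- length(s$blocks[[1]])
    if (n != 4) stop("default D_1 internal template needs blocks of 4; pass `internal`")
    J <- matrix(0, 4, 4); J[cbind(1:4, 4:1)] <- 1
    return(bcirc(circ(c(0, 1, 0, 1)), 2 * J))
  }
  stop("unknown sector type: ", s$type)
}

# planted generators of one sector, as node_perms over all_labels
sector_generators <- function(s, all_labels) {
  labs <- sector_labels(s)
  k <- length(labs)
  if (grepl("^S", s$type)) {
    lapply(seq_len(k - 1L), function(i) {
      perm_from_cycles(list(labs[c(i, i + 1L)]), all_labels)
    })
  } else if (grepl("^C", s$type)) {
    list(perm_from_cycles(list(labs), all_labels))
  } else if (s$type == "D_1") {
    b1 <- s$blocks[[1]]; b2 <- s$blocks[[2]]
    list(perm_from_cycles(lapply(seq_along(b1), function(i) c(b1[i], b2[i])),
                          all_labels))
  } else {
    stop("unknown sector type: ", s$type)
  }
}

#' Assemble a circuit with planted symmetry structure
#'
#' Builds the adjacency matrix from the spec's internal sector templates,
#' hub wiring and hub internal links, verifies that every planted
#' generator is an exact automorphism of the unperturbed circuit, and
#' applies the requested perturbation. The ground-truth sectors and group
#' names are returned alongside the circuit.
#'
#' @param spec A [plant_spec()].
#' @param directed Logical; the templates here are undirected
#'   (gap-junction style) by default.
#' @return A list with `circuit` (perturbed if requested), `ideal` (the
#'   unperturbed circuit), `truth` (tibble: `name`, `sector`,
#'   `generators`), `generators` (list of `node_perm`), and
#'   `realized_fraction`.
#' @export
plant_circuit <- function(spec, directed = FALSE) {
  stopifnot(inherits(spec, "plant_spec"))
  labels <- c(spec$hub_labels, unlist(lapply(spec$sectors, sector_labels)))
  n <- length(labels)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  nh <- length(spec$hub_labels)
  if (nh && !is.null(spec$hub_internal)) {
    A[seq_len(nh), seq_len(nh)] <- as.matrix(spec$hub_internal)
  }
  for (s in spec$sectors) {
    labs <- sector_labels(s)
    A[labs, labs] <- sector_internal(s)
    if (nh && !is.null(s$hub_weights)) {
      hw <- s$hub_weights
      W <- if (is.matrix(hw)) hw else matrix(hw, nrow = length(labs), ncol = nh,
                                             byrow = length(hw) == nh)
      A[labs, spec$hub_labels] <- W
      A[spec$hub_labels, labs] <- t(W)
    }
  }
  ideal <- circuit(A, directed = directed,
                   link_type = if (directed) "chemical" else "gap",
                   labels = labels)
  gens <- list()
  truth_rows <- list()
  groups <- c(
    lapply(spec$hub_groups, function(g) list(type = g$type, labels = g$labels)),
    lapply(spec$sectors, function(s) list(type = s$type,
                                          labels = sector_labels(s), spec = s))
  )
  for (g in groups) {
    sg <- if (is.null(g$spec)) {
      list(perm_from_cycles(list(g$labels), labels))
    } else {
      sector_generators(g$spec, labels)
    }
    for (p in sg) {
      nrm <- commutator_norm(ideal, p)
      if (nrm != 0) {
        broken <- which(A != A[unclass(p), unclass(p)], arr.ind = TRUE)[1, ]
        stop("planted generator ", format(p), " is not an automorphism; ",
             "offending link orbit includes ", labels[broken[1]], " -- ",
             labels[broken[2]])
      }
    }
    gens <- c(gens, sg)
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      name = g$type,
      sector = list(sort(g$labels)),
      generators = list(vapply(sg, format, character(1)))
    )
  }
  out_circ <- ideal
  realized <- 0
  if (spec$perturb_fraction > 0) {
    pert <- perturb(ideal, spec$perturb_fraction, spec$seed)
    out_circ <- pert$circuit
    realized <- pert$realized_fraction
  }
  list(circuit = out_circ, ideal = ideal,
       truth = dplyr::bind_rows(truth_rows),
       generators = gens, realized_fraction = realized)
}

#' Perturb a circuit by random unit-link changes
#'
#' Emulates animal-to-animal wiring variability: exactly
#' `round(fraction * M)` link units are changed, each step either
#' removing one unit from a uniformly chosen existing link unit or adding
#' one unit on a uniformly chosen node pair (no self-links). Weights move
#' in steps of 1 so the granularity matches the commutator norm's link
#' units.
#'
#' @param x A [circuit()].
#' @param fraction Fraction of the total weight M to change, in `[0, 1)`.
#' @param seed Integer seed; deterministic given it.
#' @return A list with `circuit`, `n_changed`, `realized_fraction`.
#' @export
perturb <- function(x, fraction, seed) {
  stopifnot(inherits(x, "circuit"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  M <- total_weight(x)
  k <- round(fraction * M)
  if (k == 0) {
    return(list(circuit = x, n_changed = 0L, realized_fraction = 0))
  }
  withr::local_seed(as.integer(seed))
  A <- x$A
  n <- nrow(A)
  for (step in seq_len(k)) {
    if (stats::runif(1) < 0.5 && any(A > 0)) {
      # remove one unit from an existing link, weight-proportional
      idx <- which(if (x$directed) A > 0 else (A > 0 & upper.tri(A)), arr.ind = TRUE)
      pick <- idx[sample.int(nrow(idx), 1, prob = A[idx]), ]
      A[pick[1], pick[2]] <- A[pick[1], pick[2]] - 1
      if (!x$directed) A[pick[2], pick[1]] <- A[pick[2], pick[1]] - 1
    } else {
      # add one unit on a uniform node pair
      repeat {
        ij <- sample.int(n, 2L)
        if (ij[1] != ij[2]) break
      }
      A[ij[1], ij[2]] <- A[ij[1], ij[2]] + 1
      if (!x$directed) A[ij[2], ij[1]] <- A[ij[2], ij[1]] + 1
    }
  }
  list(circuit = circuit(A, directed = x$directed, link_type = x$link_type,
                         labels = x$labels),
       n_changed = k,
       realized_fraction = k / M)
}
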