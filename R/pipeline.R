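#' End-to-end symmetry analysis of a circuit
#'
#' Runs the full analysis chain: pseudosymmetry search, exact-group
#' closure and factorization into normal subgroups, idealization,
#' per-factor orbits and imprimitivity blocks, circulant/block-circulant
#' classification with eigen-analysis, optional null-model p-values, and
#' baseline comparisons. The result prints as a Table-1-style report
#' (sector, epsilon, subgroup name, p-value) plus a block/filter
#' inventory, and is fully deterministic given `seed` and the
#' configuration.
#'
#' @param x A [circuit()] or a path to a circuit TSV.
#' @param eps_max Pseudosymmetry tolerance (default 0.25, the
#'   animal-to-animal variability bound).
#' @param null_samples Null-model ensemble size per subgroup (0 skips
#'   p-values).
#' @param seed Integer seed for the null model and baselines.
#' @param directed Passed to [read_circuit()] when `x` is a path.
#' @param annotations Optional named vector label -> functional category
#'   for sector-vs-annotation scoring.
#' @param with_baselines Compute Louvain/centrality baselines?
#' @return A `circuit_analysis` object; see [tidy.circuit_analysis()]
#'   and [glance.circuit_analysis()].
#' @export
analyze <- function(x, eps_max = 0.25, null_samples = 0, seed = 1,
                    directed = NULL, annotations = NULL,
                    with_baselines = TRUE) {
  if (is.character(x)) x <- read_circuit(x, directed = directed)
  stopifnot(inherits(x, "circuit"))
  M <- total_weight(x)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("analysis stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  exact_group <- stage("automorphism group", automorphism_group(x))
  fac <- stage("factorization", factorize(exact_group))
  candidates <- stage("pseudosymmetry search",
                      find_pseudosymmetries(x, eps_max = eps_max,
                                            factorization = fac))
  ideal <- stage("idealization", idealize(x, exact_group))

  # Per-factor imprimitivity and circulant structure, on the ideal circuit.
  # Blocks are taken from the *isolated* sector subcircuit's own symmetry
  # group: a factor like a single involution is not transitive on its
  # sector, but the sector circuit's internal symmetries are what turn
  # into a system of imprimitivity once the sector is embedded in the
  # full circuit.
  inventory <- list()
  for (f in fac$factors) {
    sec_circ <- subcircuit(ideal$circuit, f$sector)
    sec_group <- if (total_weight(sec_circ) == 0) f$subgroup else
      stage("sector symmetry", automorphism_group(sec_circ))
    orbs <- orbits(sec_group)
    orbs <- Filter(function(o) all(o %in% f$sector), orbs)
    orbs <- orbs[vapply(orbs, length, integer(1)) > 0]
    for (orb in orbs) {
      transitive_whole <- setequal(orb, f$sector)
      bss <- if (length(orb) > 1) stage("imprimitivity", block_systems(sec_group, orb))
             else list(nontrivial = list())
      primitive <- length(bss$nontrivial) == 0
      systems <- if (primitive) list(new_block_system(list(orb), orb)) else bss$nontrivial
      for (bs in systems) {
        profiles <- lapply(bs$blocks, function(b) {
          sub_m <- ideal$circuit$A[b, b, drop = FALSE]
          pr <- detect_circulant(sub_m, labels = b)
          if (is.null(pr)) pr <- nearest_pseudocirculant(sub_m, labels = b)
          pr
        })
        bc <- NULL
        if (length(bs$blocks) > 1 && length(bs$blocks) <= 4) {
          bc <- stage("block-circulant",
                      detect_block_circulant(ideal$circuit, bs$blocks,
                                             search_within = TRUE))
        }
        inventory[[length(inventory) + 1L]] <- list(
          factor_name = f$name, sector = f$sector, orbit = orb,
          transitive = transitive_whole, primitive = primitive,
          blocks = bs$blocks, profiles = profiles, block_circulant = bc
        )
      }
    }
  }

  # cross-sector block-circulant structure (e.g. the AVB/RIB command
  # block): pairs of equal-size sectors read as two blocks
  cross <- list()
  secs <- lapply(fac$factors, `[[`, "sector")
  if (length(secs) > 1) {
    for (a in seq_len(length(secs) - 1L)) {
      for (b in (a + 1L):length(secs)) {
        if (length(secs[[a]]) != length(secs[[b]]) || length(secs[[a]]) > 4) next
        bc <- detect_block_circulant(ideal$circuit, list(secs[[a]], secs[[b]]),
                                     search_within = TRUE)
        has_link <- sum(ideal$circuit$A[secs[[a]], secs[[b]]]) > 0
        if (!is.null(bc) && has_link) {
          cross[[length(cross) + 1L]] <- list(
            sectors = list(secs[[a]], secs[[b]]), profile = bc
          )
        }
      }
    }
  }

  # Table-1-style subgroup report from the candidate search
  report <- candidates
  if (null_samples > 0 && nrow(report) > 0) {
    pvals <- numeric(nrow(report))
    for (i in seq_len(nrow(report))) {
      type <- sub("^exact:", "", report$template[i])
      nr <- stage("null model",
                  subgroup_pvalue(x, type, length(report$sector[[i]]),
                                  report$epsilon[i], R = null_samples,
                                  seed = seed))
      pvals[i] <- nr$p_guarded
    }
    report$p_value <- pvals
  } else {
    report$p_value <- NA_real_
  }

  baselines <- NULL
  if (with_baselines && nrow(report) > 0) {
    baselines <- stage("baselines",
                       tryCatch(baseline_comparison(x, fac, annotations, seed = seed),
                                error = function(e) NULL))
  }

  structure(
    list(circuit = x, M = M, eps_max = eps_max,
         candidates = candidates, exact_group = exact_group,
         factorization = fac, idealization = ideal,
         inventory = inventory, cross_sector = cross, report = report,
         baselines = baselines, seed = seed,
         null_samples = null_samples),
    class = "circuit_analysis"
  )
}

#' @export
print.circuit_analysis <- function(x, ...) {
  cat(sprintf("== symmetry analysis: %d neurons, M = %d (%s %s) ==\n",
              length(x$circuit$labels), x$M,
              if (x$circuit$directed) "directed" else "undirected",
              x$circuit$link_type))
  cat(sprintf("exact symmetry group: order %d = %s\n",
              x$exact_group$order,
              paste(vapply(x$factorization$factors, `[[`, character(1), "name"),
                    collapse = " x ")))
  cat(sprintf("idealization distance: %g link units (%.1f%% of M)\n\n",
              x$idealization$distance, 100 * x$idealization$distance_fraction))
  cat("pseudosymmetry subgroups (eps_max =", x$eps_max, "):\n")
  tb <- tidy(x)
  print(tb, n = 20)
  cat("\nblock / filter inventory:\n")
  for (item in x$inventory) {
    cat(sprintf("  %s sector (%s): %s\n", item$factor_name,
                paste(item$orbit, collapse = ","),
                if (item$primitive) "primitive" else
                  sprintf("%d blocks of %d", length(item$blocks),
                          length(item$blocks[[1]]))))
    for (pr in item$profiles) {
      cat(sprintf("    circ(%s) class %s dev %.2f\n",
                  paste(pr$first_row, collapse = ","), pr$filter_class,
                  pr$deviation))
    }
  }
  invisible(x)
}

#' Tidy the subgroup report of an analysis
#'
#' One row per reported pseudosymmetry subgroup, in the style of the
#' published per-circuit tables: sector labels, template, epsilon (as a
#' fraction), p-value (guarded estimate, `NA` when the null ensemble was
#' skipped).
#'
#' @param x A `circuit_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.circuit_analysis <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    sector = vapply(r$sector, function(s) paste(s, collapse = ", "), character(1)),
    template = r$template,
    epsilon = r$epsilon,
    epsilon_pct = 100 * r$epsilon,
    exact = r$exact,
    p_value = r$p_value
  )
}

#' One-line summary of an analysis
#'
#' @param x A `circuit_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: `n_neurons`, `M`, `group_order`,
#'   `n_factors`, `factorization`, `ideal_distance`, `n_candidates`.
#' @export
glance.circuit_analysis <- function(x, ...) {
  tibble::tibble(
    n_neurons = length(x$circuit$labels),
    M = x$M,
    group_order = x$exact_group$order,
    n_factors = length(x$factorization$factors),
    factorization = paste(vapply(x$factorization$factors, `[[`,
                                 character(1), "name"), collapse = " x "),
    ideal_distance = x$idealization$distance,
    n_candidates = nrow(x$candidates)
  )
}

#' Serialize an analysis to JSON
#'
#' @param x A `circuit_analysis`.
#' @param path Optional output path.
#' @return JSON string, or `path` invisibly.
#' @export
analysis_json <- function(x, path = NULL) {
  payload <- list(
    n_neurons = length(x$circuit$labels),
    M = x$M,
    group_order = x$exact_group$order,
    factors = lapply(x$factorization$factors, function(f) {
      list(name = f$name, order = f$order, sector = f$sector)
    }),
    report = tidy(x),
    inventory = lapply(x$inventory, function(it) {
      list(factor = it$factor_name, primitive = it$primitive,
           blocks = it$blocks,
           filters = lapply(it$profiles, function(pr) {
             list(first_row = pr$first_row, class = pr$filter_class,
                  deviation = pr$deviation)
           }))
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
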