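test_that("TSV loading aggregates duplicates, symmetrizes, keeps file order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "source\ttarget\tweight\ttype",
    "AVBL\tAVBR\t1\tgap",
    "AVBL\tRIBL\t2\tgap",
    "AVBL\tRIBL\t2\tgap",   # duplicate pair: weights sum
    "RIBR\tAVBR\t1\tgap"
  ), path)
  cc <- read_circuit(path)
  expect_false(cc$directed)
  expect_identical(cc$labels, c("AVBL", "AVBR", "RIBL", "RIBR"))
  expect_equal(cc$A["AVBL", "RIBL"], 4)
  expect_equal(cc$A["RIBL", "AVBL"], 4)
  expect_equal(total_weight(cc), 6)
})

test_that("loader rejects malformed and inconsistent input", {
  expect_error(as_circuit(tibble::tibble(source = character(0),
                                         target = character(0),
                                         weight = numeric(0))),
               "empty")
  expect_error(as_circuit(tibble::tibble(source = "a", target = "b",
                                         weight = -1, type = "gap")),
               "positive integers")
  expect_error(as_circuit(tibble::tibble(source = "a", target = "b",
                                         weight = 1.5, type = "gap")),
               "positive integers")
  # both orientations declared with different weights: inconsistent
  expect_error(as_circuit(tibble::tibble(source = c("a", "b"),
                                         target = c("b", "a"),
                                         weight = c(1, 2), type = "gap")),
               "asymmetric")
  expect_error(circuit(matrix(c(0, 1, 2, 0), 2, 2), directed = FALSE),
               "symmetric")
})

test_that("write -> read round-trips bit-identically", {
  for (seed in 1:3) {
    x <- random_circuit(6, seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_circuit(x, path)
    y <- read_circuit(path)
    # same links as the original (order of labels is file-driven)
    expect_setequal(y$labels, x$labels[rowSums(x$A) > 0 | colSums(x$A) > 0])
    common <- intersect(y$labels, x$labels)
    expect_equal(y$A[common, common], x$A[common, common])
    # once in file form, read -> write -> read is bit-identical
    path2 <- withr::local_tempfile(fileext = ".tsv")
    write_circuit(y, path2)
    z <- read_circuit(path2)
    expect_identical(z$labels, y$labels)
    expect_identical(z$A, y$A)
    path3 <- withr::local_tempfile(fileext = ".tsv")
    write_circuit(z, path3)
    expect_identical(readLines(path3), readLines(path2))
  }
})

test_that("total weight follows the directed/undirected convention", {
  k4 <- command_circuit()  # unweighted complete graph on 4 nodes
  expect_equal(total_weight(k4), 6)
  d <- circuit(rbind(c(0, 3), c(0, 0)), directed = TRUE, labels = c("a", "b"))
  expect_equal(total_weight(d), 3)
  # star with 18 unit links: direct summation oracle
  star <- as_circuit(tibble::tibble(source = "hub", target = paste0("leaf", 1:18),
                                    weight = 1, type = "gap"))
  expect_equal(total_weight(star), sum(star$A) / 2)
  expect_equal(total_weight(star), 18)
})

test_that("subcircuit induces the submatrix and inherits directedness", {
  fx <- fw_circuit()
  cmd <- subcircuit(fx, c("AVBL", "AVBR", "RIBL", "RIBR"))
  expect_equal(unname(cmd$A), bcirc(circ(c(0, 1)), 2 * circ(c(1, 1))))
  expect_identical(subcircuit(fx, fx$labels)$A, fx$A)
  one <- subcircuit(fx, "VB2")
  expect_equal(unname(one$A), matrix(0, 1, 1))
  expect_error(subcircuit(fx, "NOPE"), "NOPE")
  # induced total weight can never exceed the parent's
  for (seed in 1:5) {
    labs <- withr::with_seed(seed, sample(fx$labels, 8))
    expect_lte(total_weight(subcircuit(fx, labs)), total_weight(fx))
  }
})

test_that("permutation algebra: compose, invert, cycles, support", {
  labs <- letters[1:6]
  p <- perm_from_cycles(list(c("a", "b", "c"), c("d", "e")), labs)
  expect_setequal(perm_support(p), c("a", "b", "c", "d", "e"))
  expect_identical(format(compose_perm(p, invert_perm(p))), "()")
  cy <- perm_cycles(p)
  expect_equal(length(cy), 2)
  expect_identical(cy[[1]], c("a", "b", "c"))
  # round-trip via cycles
  expect_identical(unclass(perm_from_cycles(cy, labs)), unclass(p))
  # random composition property: (pq)^-1 = q^-1 p^-1
  for (seed in 1:5) {
    q <- withr::with_seed(seed, node_perm(sample(6), labs))
    lhs <- invert_perm(compose_perm(p, q))
    rhs <- compose_perm(invert_perm(q), invert_perm(p))
    expect_identical(unclass(lhs), unclass(rhs))
  }
})
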