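test_that("commutator norm counts broken links", {
  # identity is free on any circuit
  x <- random_circuit(6, seed = 1)
  expect_equal(commutator_norm(x, perm_identity(x$labels)), 0)

  # the double swap AVBL<->RIBR, AVBR<->RIBL preserves the command circuit
  cc <- command_circuit(weighted = TRUE)
  p6 <- perm_from_cycles(list(c("AVBL", "RIBR"), c("AVBR", "RIBL")), cc$labels)
  expect_equal(commutator_norm(cc, p6), 0)
  expect_true(is_automorphism(cc, p6))

  # path a-b-c: swapping the leaves is exact, swapping b and c moves the
  # a-b link onto a-c (one broken link)
  path <- as_circuit(tibble::tibble(source = c("a", "b"), target = c("b", "c"),
                                    weight = 1, type = "gap"))
  expect_true(is_automorphism(path, perm_from_cycles(list(c("a", "c")), path$labels)))
  expect_equal(commutator_norm(path, perm_from_cycles(list(c("b", "c")), path$labels)), 1)

  # isometry: norm of the inverse equals the norm
  for (seed in 1:5) {
    x <- random_circuit(7, seed = seed)
    p <- withr::with_seed(seed, node_perm(sample(7), x$labels))
    expect_equal(commutator_norm(x, p), commutator_norm(x, invert_perm(p)))
  }
})

test_that("epsilon reproduces the one-link-in-18 calibration", {
  cc <- eps_calibration_circuit()
  expect_equal(total_weight(cc), 18)
  p <- perm_from_cycles(list(c("DB5", "DB6")), cc$labels)
  ps <- pseudosymmetry(cc, p)
  expect_equal(ps$norm, 1)
  expect_equal(ps$epsilon, 1 / 18)
  expect_true(ps$plausible)
  # exact automorphism scores 0
  q <- perm_from_cycles(list(c("x1", "x2"), c("y1", "y2")), cc$labels)
  expect_equal(pseudosymmetry(cc, q)$epsilon, 0)
})

test_that("reversing a directed edge of weight w scores 2w", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 5
  A[2, 3] <- 1
  x <- circuit(A, directed = TRUE, labels = c("a", "b", "c"))
  p <- perm_from_cycles(list(c("a", "b")), x$labels)
  # brute-force oracle: full ordered sum
  img <- unclass(p)
  expect_equal(commutator_norm(x, p), sum(abs(x$A - x$A[img, img])))
})

test_that("automorphism group matches exhaustive and BLISS oracles", {
  # weighted command circuit: 8 of the 24 permutations, the square group
  cc <- command_circuit(weighted = TRUE)
  g <- automorphism_group(cc)
  expect_equal(group_order(g), 8)
  expect_equal(identify_group(g), "D_8")
  expect_equal(length(brute_force_automorphisms(cc)), 8)
  expect_equal(igraph_automorphism_count(cc), 8)

  # unweighted K4: the full symmetric group
  expect_equal(group_order(automorphism_group(command_circuit())), 24)

  # undirected 4-cycle (the F matrix is its adjacency)
  ring <- circuit(circ(c(0, 1, 0, 1)), directed = FALSE,
                  labels = paste0("r", 1:4))
  expect_equal(group_order(automorphism_group(ring)), 8)

  # random circuits agree with the n! filter
  for (seed in 1:4) {
    x <- random_circuit(6, seed = seed)
    g <- automorphism_group(x)
    expect_equal(group_order(g), length(brute_force_automorphisms(x)))
    # every returned element is exact, and the set is closed
    expect_true(all(vapply(g$elements, function(p) commutator_norm(x, p) == 0,
                           logical(1))))
    cl <- closure(g$generators)
    expect_equal(group_order(cl), group_order(g))
  }

  # directed case against the n! filter
  xd <- random_circuit(5, seed = 9, directed = TRUE)
  expect_equal(group_order(automorphism_group(xd)),
               length(brute_force_automorphisms(xd)))

  expect_error(automorphism_group(fw_circuit(), max_nodes = 10), "sector")
})

test_that("the forward fixture group matches the BLISS oracle", {
  expect_equal(group_order(fw_group()), 3840)
  expect_equal(igraph_automorphism_count(fw_circuit()), 3840)
})

test_that("pseudosymmetry search finds planted structure deterministically", {
  fx <- fw_circuit()
  res <- find_pseudosymmetries(fx, eps_max = 0.25,
                               factorization = fw_factorization())
  # exact planted subgroups surface with epsilon 0
  exact <- res[res$exact, ]
  expect_setequal(
    vapply(exact$sector, function(s) paste(sort(s), collapse = ","), character(1)),
    c("AVBL,AVBR", "RIBL,RIBR", "DB5,DB6,DB7,VB10,VB11",
      "DB1,DB2,DB3,VB1,VB2,VB4,VB5,VB6", "VB3,VB7", "VB8,VB9")
  )
  expect_true(all(res$epsilon <= 0.25))
  # deterministic output
  res2 <- find_pseudosymmetries(fx, eps_max = 0.25,
                                factorization = fw_factorization())
  expect_identical(res$template, res2$template)
  expect_identical(res$epsilon, res2$epsilon)

  # eps_max = 0 keeps only the exact automorphism structure
  res0 <- find_pseudosymmetries(fx, eps_max = 0,
                                factorization = fw_factorization())
  expect_true(all(res0$exact))

  # identically hub-wired 5 nodes: the S_5 template is exact
  s5 <- res[res$template == "exact:S_5", ]
  expect_equal(nrow(s5), 1)
  expect_equal(s5$epsilon, 0)
})

test_that("a planted C_2 pair perturbed by one link unit scores its epsilon", {
  # pair u,v wired identically into a 20-unit circuit (heterogeneous
  # weighted-path filler so the rest carries no accidental symmetry),
  # then one unit removed
  edges <- tibble::tibble(
    source = c("u", "v", "u", "v", "h1", "f1", "f2", "f3", "f4", "f5", "f6"),
    target = c("h1", "h1", "h2", "h2", "f1", "f2", "f3", "f4", "f5", "f6", "h2"),
    weight = c(1, 1, 1, 1, 4, 3, 3, 2, 2, 1, 1), type = "gap"
  )
  x <- as_circuit(edges)
  expect_equal(total_weight(x), 20)
  A <- x$A
  A["u", "h2"] <- 0
  A["h2", "u"] <- 0
  x2 <- circuit(A, directed = FALSE, labels = x$labels)
  p <- perm_from_cycles(list(c("u", "v")), x2$labels)
  expect_equal(pseudosymmetry(x2, p)$epsilon, 1 / 19)
  # transposition scan reports it
  res <- find_pseudosymmetries(x2, eps_max = 0.1)
  pair_rows <- res[vapply(res$sector, function(s) setequal(s, c("u", "v")),
                          logical(1)), ]
  expect_gte(nrow(pair_rows), 1)
  expect_equal(min(pair_rows$epsilon), 1 / 19)
})

test_that("pseudosymmetry non-closure is possible and tolerated", {
  # two single-swap pseudosymmetries can compose into a worse permutation
  x <- eps_calibration_circuit()
  p <- perm_from_cycles(list(c("DB5", "DB6")), x$labels)
  q <- perm_from_cycles(list(c("DB6", "x1")), x$labels)
  eps_p <- pseudosymmetry(x, p)$epsilon
  eps_q <- pseudosymmetry(x, q)$epsilon
  eps_pq <- pseudosymmetry(x, compose_perm(p, q))$epsilon
  expect_gt(eps_pq, max(eps_p, eps_q))
})
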