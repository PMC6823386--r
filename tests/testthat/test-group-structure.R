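test_that("closure materializes the generated group", {
  labs <- paste0("n", 1:5)
  expect_equal(group_order(closure(perm_from_cycles(list(c("n1", "n2")), labs))), 2)
  # square rotation + reflection: 8 elements
  sq <- paste0("s", 1:4)
  rot <- perm_from_cycles(list(sq), sq)
  refl <- perm_from_cycles(list(c("s2", "s4")), sq)
  expect_equal(group_order(closure(list(rot, refl))), 8)
  # all transpositions on 5 labels generate 5! elements
  gens <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    gens[[length(gens) + 1L]] <- perm_from_cycles(list(labs[c(i, j)]), labs)
  }
  expect_equal(group_order(closure(gens)), 120)
  expect_error(closure(gens, cap = 50), "cap exceeded")
  # group axioms hold on the closed set
  g <- closure(list(rot, refl))
  keys <- vapply(g$elements, symcirc:::perm_key, character(1))
  expect_true(symcirc:::perm_key(perm_identity(sq)) %in% keys)
  for (e in g$elements) {
    expect_true(symcirc:::perm_key(invert_perm(e)) %in% keys)
    expect_true(symcirc:::perm_key(compose_perm(e, rot)) %in% keys)
  }
})

test_that("normality is coset equality, checked by conjugation", {
  labs <- c("a", "b", "c")
  s3 <- closure(list(perm_from_cycles(list(c("a", "b")), labs),
                     perm_from_cycles(list(c("b", "c")), labs)))
  triv <- perm_group(elements = list(perm_identity(labs)), labels = labs)
  expect_true(is_normal(triv, s3))
  # a single transposition is not normal in S_3 (explicit conjugation)
  sub <- closure(perm_from_cycles(list(c("a", "b")), labs))
  expect_false(is_normal(sub, s3))
  # the alternating rotation subgroup is
  rot3 <- closure(perm_from_cycles(list(c("a", "b", "c")), labs))
  expect_true(is_normal(rot3, s3))
  # subgroup membership is enforced
  other <- closure(perm_from_cycles(list(c("a", "b")), c("a", "b", "d")))
  expect_error(is_normal(other, s3))
  # the planted involution factor is normal in the fixture group
  fac <- fw_factorization()
  d1 <- fac$factors[[which(vapply(fac$factors, `[[`, character(1), "name") == "D_1")]]
  expect_true(is_normal(d1$subgroup, fw_group()))
})

test_that("factorization splits disjoint sectors and verifies", {
  labs <- letters[1:4]
  g <- closure(list(perm_from_cycles(list(c("a", "b")), labs),
                    perm_from_cycles(list(c("c", "d")), labs)))
  fac <- factorize(g)
  expect_false(fac$residual)
  expect_equal(length(fac$factors), 2)
  expect_identical(lapply(fac$factors, `[[`, "sector"),
                   list(c("a", "b"), c("c", "d")))
  expect_identical(vapply(fac$factors, `[[`, character(1), "name"),
                   c("C_2", "C_2"))

  # S_3 with overlapping supports stays a single factor
  labs3 <- c("a", "b", "c")
  s3 <- closure(list(perm_from_cycles(list(c("a", "b")), labs3),
                     perm_from_cycles(list(c("b", "c")), labs3)))
  fac3 <- factorize(s3)
  expect_equal(length(fac3$factors), 1)
  expect_identical(fac3$factors[[1]]$name, "S_3")
  expect_false(fac3$residual)
})

test_that("the fixture factorizes into the six published sectors", {
  fac <- fw_factorization()
  expect_false(fac$residual)
  expect_equal(length(fac$factors), 6)
  tb <- tidy(fac)
  expect_identical(tb$name, c("C_2", "C_2", "S_5", "D_1", "C_2", "C_2"))
  expect_identical(tb$sector[[3]], sort(c("DB5", "DB6", "DB7", "VB10", "VB11")))
  expect_identical(tb$sector[[4]], sort(c(fw_b1(), fw_b2())))
  expect_identical(tb$sector[[5]], c("VB3", "VB7"))
  expect_identical(tb$sector[[6]], c("VB8", "VB9"))
  # re-multiplying the factors recovers the group order
  gens <- unlist(lapply(fac$factors, function(f) f$subgroup$generators),
                 recursive = FALSE)
  expect_equal(group_order(closure(gens, cap = 1e4)), group_order(fw_group()))
  expect_equal(prod(tb$order), group_order(fw_group()))
})

test_that("group naming follows the field's conventions", {
  sq <- paste0("s", 1:4)
  d8 <- closure(list(perm_from_cycles(list(sq), sq),
                     perm_from_cycles(list(c("s2", "s4")), sq)))
  expect_identical(identify_group(d8), "D_8")
  expect_identical(identify_group(d8, dihedral_by_order = FALSE), "D_4")
  labs <- letters[1:5]
  expect_identical(identify_group(closure(perm_from_cycles(list(c("a", "b")), labs))),
                   "C_2")
  # involution moving four points: the D_1 convention
  inv <- closure(perm_from_cycles(list(c("a", "b"), c("c", "d")), labs))
  expect_identical(identify_group(inv), "D_1")
  expect_identical(identify_group(closure(perm_from_cycles(list(letters[1:5]), labs))),
                   "C_5")
  # naming is stable under relabeling
  labs2 <- paste0("z", 1:5)
  inv2 <- closure(perm_from_cycles(list(c("z5", "z3"), c("z1", "z4")), labs2))
  expect_identical(identify_group(inv2), "D_1")
})
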