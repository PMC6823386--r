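test_that("circulant construction and detection", {
  expect_equal(circ(c(0, 1)), rbind(c(0, 1), c(1, 0)))
  expect_equal(bcirc(circ(c(0, 1)), circ(c(1, 1))),
               rbind(c(0, 1, 1, 1), c(1, 0, 1, 1), c(1, 1, 0, 1), c(1, 1, 1, 0)))

  # the filter catalogue
  h <- detect_circulant(rbind(c(0, 1), c(1, 0)))
  expect_equal(h$first_row, c(0, 1))
  expect_identical(h$filter_class, "H")
  l <- detect_circulant(rbind(c(1, 1), c(1, 1)))
  expect_identical(l$filter_class, "L")
  expect_null(detect_circulant(rbind(c(0, 1), c(0, 0))))

  f <- detect_circulant(circ(c(0, 1, 0, 1)))
  expect_identical(f$filter_class, "F")

  # detection is invariant under relabeling: scramble a circulant
  for (seed in 1:5) {
    ord <- withr::with_seed(seed, sample(4))
    scr <- circ(c(0, 1, 0, 1))[ord, ord]
    pr <- detect_circulant(scr, labels = paste0("m", 1:4))
    expect_false(is.null(pr))
    expect_equal(pr$first_row, c(0, 1, 0, 1))
  }
})

test_that("nearest pseudocirculant measures the deviation fraction", {
  expect_equal(nearest_pseudocirculant(circ(c(0, 1, 0, 1)))$deviation, 0)
  # remove one undirected link from the 4-link F ring: deviation 1/4
  A <- circ(c(0, 1, 0, 1))
  A[1, 2] <- A[2, 1] <- 0
  pr <- nearest_pseudocirculant(A)
  expect_equal(pr$deviation, 0.25)
  # all-zero block: the trivial zero circulant
  z <- nearest_pseudocirculant(matrix(0, 3, 3))
  expect_identical(z$filter_class, "zero")
  expect_equal(z$deviation, 0)
})

test_that("block-circulant structure is found in the shipped fixtures", {
  # command circuit: bcirc(H, L)
  cmd <- command_circuit()
  bc <- detect_block_circulant(cmd, list(c("AVBL", "AVBR"), c("RIBL", "RIBR")))
  expect_false(is.null(bc))
  expect_equal(bc$components[[1]], circ(c(0, 1)), ignore_attr = TRUE)
  expect_equal(bc$components[[2]], circ(c(1, 1)), ignore_attr = TRUE)
  expect_identical(bc$component_profiles[[1]]$filter_class, "H")
  expect_identical(bc$component_profiles[[2]]$filter_class, "L")

  # forward motor blocks: A_1 = F, over the printed orderings
  fx <- fw_circuit()
  bcm <- detect_block_circulant(fx, list(fw_b1(), fw_b2()))
  expect_false(is.null(bcm))
  expect_equal(bcm$components[[1]], circ(c(0, 1, 0, 1)), ignore_attr = TRUE)
  expect_identical(bcm$component_profiles[[1]]$filter_class, "F")
  # with sorted blocks the orderings are searched automatically
  bcs <- detect_block_circulant(fx, list(sort(fw_b1()), sort(fw_b2())),
                                search_within = TRUE)
  expect_false(is.null(bcs))

  # AIB/RIM backward block: bcirc(circ(0,0), circ(1,0))
  ar <- aib_rim_circuit()
  bca <- detect_block_circulant(ar, list(c("AIBL", "AIBR"), c("RIML", "RIMR")))
  expect_false(is.null(bca))
  expect_equal(bca$components[[1]], circ(c(0, 0)), ignore_attr = TRUE)
  expect_equal(bca$components[[2]], circ(c(1, 0)), ignore_attr = TRUE)

  expect_error(detect_block_circulant(cmd, list(c("AVBL", "AVBR"), "RIBL")),
               "equal sizes")
})

test_that("circulant eigenstructure is the DFT of the first row", {
  ce <- circulant_eigen(c(0, 1, 0, 1))
  expect_setequal(ce$values, c(2, 0, 0, -2))
  # eigenvectors match the published modes up to sign
  V <- ce$vectors
  expect_equal(abs(V[, ce$values == 2]), rep(1 / 2, 4))
  vm2 <- V[, ce$values == -2]
  expect_equal(abs(vm2), rep(1 / 2, 4))
  expect_equal(vm2[1] * vm2[2], -1 / 4)  # alternating signs
  # 2x2 closed forms
  expect_setequal(circulant_eigen(c(1, 1))$values, c(2, 0))
  expect_setequal(circulant_eigen(c(0, 1))$values, c(1, -1))

  # dense eigen-decomposition oracle, l up to 16
  for (l in c(3, 4, 5, 8, 16)) {
    fr <- withr::with_seed(l, sample(0:3, l, replace = TRUE))
    fr[1] <- 0
    fr[-1] <- pmax(fr[-1], rev(fr[-1]))  # symmetric row
    ce <- circulant_eigen(fr)
    dense <- eigen(circ(fr), symmetric = TRUE)
    expect_equal(sort(Re(ce$values)), sort(dense$values), tolerance = 1e-9)
    # every reported vector is a genuine eigenvector
    for (k in seq_len(l)) {
      expect_equal(as.numeric(circ(fr) %*% ce$vectors[, k]),
                   Re(ce$values[k]) * ce$vectors[, k], tolerance = 1e-9)
    }
    # trace preservation: eigenvalues sum to l * c_1
    expect_equal(sum(Re(ce$values)), l * fr[1], tolerance = 1e-9)
  }

  # asymmetric first row: complex conjugate pairs, still eigenvectors
  fr <- c(0, 1, 0, 0, 2)
  ce <- circulant_eigen(fr)
  for (k in 1:5) {
    expect_equal(as.complex(circ(fr) %*% ce$vectors[, k]),
                 as.complex(ce$values[k] * ce$vectors[, k]), tolerance = 1e-9)
  }

  expect_error(circulant_eigen(nearest_pseudocirculant(
    rbind(c(0, 1), c(0, 0)))), "deviation")
})

test_that("filter classification covers the catalogue and beyond", {
  expect_identical(classify_filter(c(0, 1))$class, "H")
  expect_identical(classify_filter(c(1, 1))$class, "L")
  expect_identical(classify_filter(c(0, 1, 0, 1))$class, "F")
  expect_identical(classify_filter(c(0, 0, 0))$class, "zero")
  other <- classify_filter(c(0, 1, 1))
  expect_identical(other$class, "other")
  expect_equal(other$response, Mod(stats::fft(c(0, 1, 1))))
})
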