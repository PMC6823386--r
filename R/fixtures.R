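#' The 4-neuron command interneuron circuit
#'
#' The gap-junction circuit on AVBL, AVBR, RIBL, RIBR. Unweighted
#' (`weighted = FALSE`), it is the block-circulant matrix
#' `bcirc(circ(0,1), circ(1,1))` — a complete graph whose symmetry group
#' is the full symmetric group of order 24. With `weighted = TRUE` the
#' within-pair links carry weight `pair_weight` and the four cross links
#' `cross_weight`; distinct weights cut the symmetry down to the 8
#' automorphisms of a square (the dihedral group D_8).
#'
#' @param weighted Distinguish pair and cross links?
#' @param pair_weight,cross_weight Integer weights used when `weighted`.
#' @return A [circuit()].
#' @export
command_circuit <- function(weighted = FALSE, pair_weight = 1, cross_weight = 2) {
  labs <- c("AVBL", "AVBR", "RIBL", "RIBR")
  pw <- if (weighted) pair_weight else 1
  cw <- if (weighted) cross_weight else 1
  A <- bcirc(pw * circ(c(0, 1)), cw * circ(c(1, 1)))
  circuit(A, directed = FALSE, link_type = "gap", labels = labs)
}

#' Plant spec for the ideal forward gap-junction circuit
#'
#' A 21-neuron reconstruction of the ideal forward locomotion
#' gap-junction circuit, assembled so that its exact symmetry group is
#' the direct product
#' `[C_2 x C_2] x [S_5 x D_1 x C_2 x C_2]` of order
#' 1920 = 2 * 2 * 120 * 2 * 2 * 2:
#'
#' * command hubs AVBL/AVBR and RIBL/RIBR, within-pair links weight 1,
#'   cross links weight 2;
#' * a primitive S_5 motor sector (DB5, DB6, DB7, VB10, VB11) wired
#'   identically to the AVB hubs, with an all-zero internal block;
#' * the D_1 motor sector with imprimitivity blocks
#'   (VB2, DB3, DB2, VB1) and (DB1, VB4, VB5, VB6), each an internal
#'   `circ(0,1,0,1)` 4-cycle, cross-paired antidiagonally (weight 2) so
#'   the involution sigma: (VB2,DB3,DB2,VB1) <-> (DB1,VB4,VB5,VB6) is
#'   exact; hub weights are staggered by sigma-orbit (3, 1, 2, 0) to pin
#'   the sector group to exactly {id, sigma};
#' * the (VB3, VB7) and (VB8, VB9) pairs, wired to both AVB hubs at
#'   weights 6 and 7 respectively (the weight asymmetry that separates
#'   them from the RIB interneuron pair).
#'
#' The weighted full matrix is a reconstruction: block memberships,
#' internal 4-cycles and the printed involution come from the published
#' ideal circuit, but cross and hub weights are synthetic choices that
#' realize exactly the published factor structure.
#'
#' @return A [plant_spec()].
#' @export
forward_ideal_spec <- function() {
  b1 <- c("VB2", "DB3", "DB2", "VB1")
  b2 <- c("DB1", "VB4", "VB5", "VB6")
  # hub weights by sigma-orbit: (VB2,DB1)=3, (DB3,VB4)=1, (DB2,VB5)=2,
  # (VB1,VB6)=0; rows in block order b1 then b2
  hw <- cbind(c(3, 1, 2, 0, 3, 1, 2, 0), c(3, 1, 2, 0, 3, 1, 2, 0))
  hw <- cbind(AVBL = hw[, 1], AVBR = hw[, 2], RIBL = 0, RIBR = 0)
  s5 <- c("DB5", "DB6", "DB7", "VB10", "VB11")
  plant_spec(
    sectors = list(
      list(type = "S_5", labels = s5,
           hub_weights = cbind(AVBL = rep(1, 5), AVBR = 1, RIBL = 0, RIBR = 0)),
      list(type = "D_1", blocks = list(b1, b2), hub_weights = hw),
      list(type = "C_2", labels = c("VB3", "VB7"), internal = matrix(0, 2, 2),
           hub_weights = cbind(AVBL = c(6, 6), AVBR = 6, RIBL = 0, RIBR = 0)),
      list(type = "C_2", labels = c("VB8", "VB9"), internal = matrix(0, 2, 2),
           hub_weights = cbind(AVBL = c(7, 7), AVBR = 7, RIBL = 0, RIBR = 0))
    ),
    hub_labels = c("AVBL", "AVBR", "RIBL", "RIBR"),
    hub_internal = bcirc(circ(c(0, 1)), 2 * circ(c(1, 1))),
    hub_groups = list(
      list(type = "C_2", labels = c("AVBL", "AVBR")),
      list(type = "C_2", labels = c("RIBL", "RIBR"))
    )
  )
}

#' The ideal forward gap-junction circuit fixture
#'
#' Assembles [forward_ideal_spec()] into a circuit. See that help page
#' for the construction and the caveat that weights are a synthetic
#' reconstruction.
#'
#' @return A [circuit()] on 21 neurons.
#' @export
forward_ideal_circuit <- function() {
  plant_circuit(forward_ideal_spec())$circuit
}

#' The AIB/RIM backward imprimitivity block
#'
#' The 4-neuron block of the backward gap-junction circuit:
#' `bcirc(circ(0,0), circ(1,0))` over blocks (AIBL, AIBR) and
#' (RIML, RIMR) — no links within either pair, identity coupling across
#' them (AIBL-RIML and AIBR-RIMR). The planted D_1 involution swaps both
#' pairs simultaneously.
#'
#' @return A [circuit()].
#' @export
aib_rim_circuit <- function() {
  labs <- c("AIBL", "AIBR", "RIML", "RIMR")
  A <- bcirc(circ(c(0, 0)), circ(c(1, 0)))
  circuit(A, directed = FALSE, link_type = "gap", labels = labs)
}
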