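# Shared fixtures, computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fw_circuit <- function() {
  if (is.null(.fixture_cache$fw)) .fixture_cache$fw <- forward_ideal_circuit()
  .fixture_cache$fw
}

fw_group <- function() {
  if (is.null(.fixture_cache$fw_group)) {
    .fixture_cache$fw_group <- automorphism_group(fw_circuit())
  }
  .fixture_cache$fw_group
}

fw_factorization <- function() {
  if (is.null(.fixture_cache$fw_fac)) {
    .fixture_cache$fw_fac <- factorize(fw_group())
  }
  .fixture_cache$fw_fac
}

# the published D_1 motor imprimitivity blocks, in printed order
fw_b1 <- function() c("VB2", "DB3", "DB2", "VB1")
fw_b2 <- function() c("DB1", "VB4", "VB5", "VB6")

# circuit with M = 18 where one transposition misplaces exactly one unit
# link: DB5 and DB6 share a hub link to AVBL but only DB5 reaches AVBR
eps_calibration_circuit <- function() {
  edges <- tibble::tibble(
    source = c("DB5", "DB5", "DB6", paste0("x", 1:15)),
    target = c("AVBL", "AVBR", "AVBL", paste0("y", 1:15)),
    weight = 1,
    type = "gap"
  )
  as_circuit(edges)
}
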