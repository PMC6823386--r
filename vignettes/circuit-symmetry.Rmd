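---
title: "Symmetry groups, imprimitivity blocks and circulant filters in small neural circuits"
author: "symcirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry groups, imprimitivity blocks and circulant filters in small neural circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcirc)
```

## The model

A small neural circuit is a labeled weighted graph: neurons are nodes and
`A[i, j]` counts the connections from neuron `i` to neuron `j`. Gap
junctions are undirected (`A` symmetric); chemical synapses are directed.
The package asks one structural question about such a circuit: which
relabelings of the neurons leave the wiring (approximately) unchanged, and
what does the algebra of those relabelings say about the circuit's
function?

A permutation $P$ of the neurons is an **automorphism** when $PAP^{-1} =
A$ — equivalently the commutator $[P, A] = PA - AP$ vanishes. Biological
wiring is not that clean: connectomes of individual animals differ by
roughly 25% of their connections, so exact symmetry is an idealization.
The package therefore scores every permutation by the **commutator norm**

$$\lVert [P, A] \rVert \;=\; \sum_{ij} \lvert A_{ij} - A_{P(i)P(j)} \rvert,$$

normalized into the dimensionless **uncertainty constant**
$\varepsilon = \lVert [P, A]\rVert / M$, where $M$ is the circuit's total
link weight (sum over unordered pairs for undirected circuits, ordered
pairs for directed ones). A permutation with $\varepsilon$ below a
tolerance — 0.25 by default, the animal-to-animal variability — is a
**pseudosymmetry**: it preserves at least a fraction $1 - \varepsilon$ of
the wiring.

### Units of the norm

For undirected circuits the ordered double sum above counts every broken
link four times: the lost link and the spuriously gained one, each in both
orientations. The package divides by 4 so that **one misplaced undirected
unit link scores exactly 1**, and a transposition that misplaces a single
link in a circuit of 18 weighted links has $\varepsilon = 1/18 \approx
5.5\%$:

```{r calibration}
edges <- tibble::tibble(
  source = c("DB5", "DB5", "DB6", paste0("x", 1:15)),
  target = c("AVBL", "AVBR", "AVBL", paste0("y", 1:15)),
  weight = 1, type = "gap")
cc <- as_circuit(edges)
p <- perm_from_cycles(list(c("DB5", "DB6")), cc$labels)
pseudosymmetry(cc, p)
```

Directed circuits keep the full ordered sum (reversing a directed edge of
weight $w$ scores $2w$, since both ordered entries change). This choice is
deliberate: the undirected convention is what makes the printed
one-broken-link example come out at $1/18$ rather than $2/18$; an
alternative convention that counts the loss and the gain separately would
double every undirected $\varepsilon$.

## Finding symmetries

`automorphism_group()` enumerates all exact automorphisms by backtracking
over a color-refined partition: nodes are first split by iterated weighted
neighborhood signatures, then a depth-first search assigns images inside
color classes with partial adjacency-consistency pruning. The suite
cross-checks the enumeration against two independent oracles — exhaustive
$n!$ filtering for $n \le 7$, and BLISS (via igraph) on a colored
edge-subdivision encoding of the weighted graph — so the search itself is
never its own referee.

`find_pseudosymmetries()` then relaxes exactness in three deterministic
stages: the exact group and its factors; all transpositions with
$\varepsilon$ below tolerance; and a template stage that clusters labels
with mutually small swap costs into candidate sectors and tests symmetric
(`S_k`, all transpositions), cyclic (`C_k`, greedy cheapest rotation) and
involution (`D_1`, greedy pairing) subgroup templates. A subgroup's
$\varepsilon$ is reported conservatively as the **maximum** over its
generators (the mean is also recorded); full enumeration of the
permutation space is never attempted beyond the exact stage, since the
subgroup types observed in locomotion circuits are exactly these
templates. Greedy cycle orderings and pairings can in principle miss the
optimal template on adversarial inputs; ties and output order are fully
lexicographic so results are reproducible.

## Factorization into sectors

The exact symmetry group of a locomotion circuit factorizes as a direct
product of **normal subgroups**, each moving its own disjoint **sector**
of neurons. `factorize()` finds this decomposition from the group itself:
orbits are merged whenever the group's joint action on two orbit sets has
fewer distinct restrictions than the product of the marginal counts, and
each final sector's factor is the set of elements supported inside it.
The result is verified (marginal counts, order product); factors of a
verified direct product are automatically normal, and `is_normal()`
checks coset equality explicitly in the tests. Groups are named by
structure: cyclic `C_n`, symmetric `S_k` on the moved points, dihedral
`D_n` labeled by *order* (the square's group is `D_8`), and — following
the field's convention for connectome tables — an order-2 involution
moving more than two points is `D_1` while a plain transposition is
`C_2`.

```{r fixture}
fx <- forward_ideal_circuit()
fac <- factorize(automorphism_group(fx))
tidy(fac)
```

This 21-neuron fixture is a reconstruction of the ideal forward
gap-junction locomotion circuit. Its block memberships, the two motor
4-cycles, the involution pairing them and the published factor structure
`[C_2 x C_2] x [S_5 x D_1 x C_2 x C_2]` are reproduced exactly; the cross
and hub weights, however, are synthetic choices (documented in
`?forward_ideal_spec`) made so that the planted group — and nothing more —
is the exact symmetry group. The printed cross-block of the motor sector
is asymmetric as published, which an undirected matrix cannot literally
realize; the fixture uses its symmetrized closure at weight 2, the choice
that keeps the published involution exact while pinning the sector's
internal symmetry to exactly `{id, sigma}`.

## Blocks of imprimitivity and circulant filters

Inside a sector, a **block of imprimitivity** is a neuron set that every
group element maps wholly onto itself or wholly onto a disjoint set.
`minimal_blocks()` implements the standard union-find refinement (merge a
seed pair, propagate images until stable) for transitive actions, and
`block_systems()` collects all minimal systems over seed pairs, checked
against exhaustive partition search in the tests.

One subtlety is which group acts. A factor such as a single involution is
not transitive on its sector, and no seed pair can then grow the published
size-4 blocks under it. The pipeline instead takes the **isolated sector
subcircuit's own automorphism group** — transitive on the motor sector,
order 16 — whose minimal system from the seed pair (VB2, DB3) is exactly
the published pair of blocks; integrating the sector into the full circuit
is what demotes those internal symmetries to a block system. Orbit
partitions are additionally available as an alternative block system.

Blocks are then matched to **circulant matrices** (each row a right-shift
of the previous): `circ(0, 1)` acts as a high-pass filter H, `circ(1, 1)`
as a low-pass filter L, and `circ(0, 1, 0, 1)` (F) as a subsampling
kernel supporting oscillation between its extreme eigenvalues. Nested
structure is captured by block-circulant matrices; the 4-neuron command
circuit is `bcirc(H, L)`:

```{r command}
cmd <- command_circuit()
detect_block_circulant(cmd, list(c("AVBL", "AVBR"), c("RIBL", "RIBR")))
```

Eigenvalues of a circulant are the DFT of its first row
(`circulant_eigen()`, checked against dense eigendecomposition); for F
they are $\{-2, 2, 0, 0\}$ with Fourier-mode eigenvectors. On raw (not
idealized) circuits, `nearest_pseudocirculant()` reports the closest
circulant and the fraction of differing link weight; its deviation
denominator is the larger of the two total weights, so both missing and
spurious links count against the match.

## Idealization

`idealize()` constructs the $\varepsilon \to 0$ circuit on which a chosen
group becomes exact: the adjacency matrix is averaged over the group and
rounded **orbit-wise** (one value per link orbit, halves up), which
guarantees exact invariance of the rounded output and, per orbit, an
L1-minimal integer repair. Idempotence and exact symmetry of the result
are asserted as properties in the tests.

## Statistical significance

A pseudosymmetry is only interesting if random circuits with the same
degree structure rarely admit one as good.
`randomize_degree_preserving()` implements weighted double-edge swaps on
the unit-link multigraph (weights travel with links; self-links are
rejected; directed swaps preserve in- and out-strengths), with
`10 * M` attempted swaps by default. `subgroup_pvalue()` searches each of
`R` null circuits for the best subgroup of the same template type and
sector size *anywhere* in the circuit — the null hypothesis is "a subgroup
this good arises by chance somewhere", not "at these labels" — and reports
`p = #{eps* <= eps} / R` together with the guarded estimate
`(1 + #) / (R + 1)`. "Same degree sequence" is read as the weighted
(strength) sequence, since links carry multiplicities. Desk-scale runs in
the tests use `R` between 15 and 60; published-scale p-values down to
$10^{-6}$ require ensembles of $10^6$, which the same code supports by
raising `R`.

## Linear filter dynamics

The detected architecture — command hubs feeding motor blocks — maps onto
the standard linear rate model
$\tau \dot{v} = -v + M_{rec} v + W u$
(`linear_filter_model()`): `W` is the feedforward matrix (the all-ones
$4 \times 2$ wall from the AVB hubs into a motor block), `M_rec` the
recurrent block (typically a circulant filter), `u` the command input.
`steady_state()` solves $(I - M_{rec})^{-1} W u$ when no recurrent
eigenvalue equals 1; `simulate_filter()` integrates with classical RK4
(`dt < tau / 2` guard); `mode_projection()` projects trajectories on the
Fourier eigenbasis, each mode evolving as $e^{(\lambda - 1) t / \tau}$.
The F filter's $\lambda = 2$ mode is linearly *unstable* under this model;
the package reports per-mode stability rather than imposing saturation,
staying faithful to the linear formulation. $\tau$ defaults to 1 and all
times are in units of $\tau$.

## Baselines

`modularity_partition()` (seeded multi-restart Louvain, weighted,
symmetrized for directed circuits) and `eigenvector_centrality()`
(power iteration on $A + I$; the shift removes bipartite oscillation
without changing the principal eigenvector) provide the standard
alternatives; `partition_agreement()` scores partitions by the adjusted
Rand index. On the fixture, Louvain mixes the AVB hubs into the motor
communities while the factorization separates them — the qualitative
comparison the symmetry analysis is designed to win.

## The synthetic generator, and what passing tests mean

`plant_spec()`/`plant_circuit()` assemble circuits from sector templates
(identically-wired `S_n` sectors with empty internal blocks, `C_n` rings,
`D_1` block pairs with circulant internals), hub wiring and hub groups,
verifying by construction that every planted generator is exact.
`perturb()` changes exactly `round(fraction * M)` link units (weight
steps of 1, uniformly chosen additions/removals, mandatory seed), so the
perturbation granularity matches the norm's. The default perturbation
level for robustness properties is 0.25, the reported biological
variability; test ensembles use 40 seeds.

The generator emulates the *structure* the analysis targets — planted
product groups, circulant blocks, hub feedforward, uniform link noise. It
does not emulate spatially correlated wiring noise, degree-dependent
variability, inhibitory/excitatory sign structure, or whole-connectome
scale, so green tests certify the machinery (recovery of planted
structure at the stated noise levels), not performance on any real
connectome. Analyses of real data additionally face the uncertainty of
connectome reconstruction itself, which the single-number $\varepsilon$
only summarizes.

## Numerical and design choices

* Exact integer arithmetic throughout the norm and group code; the only
  floating-point surfaces are eigen-analysis, centrality and p-values.
* Tie-breaks (search output order, pseudocirculant first rows, orderings)
  are lexicographic; all stochastic components take explicit seeds.
* The automorphism search is guarded at 64 nodes; sector-wise analysis is
  the intended route for larger circuits.
* Problem sizes in the test suite (21-neuron fixture, null ensembles of
  tens, 8-node property circuits) are chosen so the full suite runs in
  about a minute while still exercising every published structure;
  every quantitative claim in this vignette is computed by the suite or
  the acceptance script, not transcribed.
* Degenerate inputs fail loudly: empty edge lists, non-square blocks,
  non-transitive actions, singular steady states and oversized closures
  raise errors naming the problem.

## Known limitations

* Pseudosymmetry search beyond the `C/S/D` templates (arbitrary subgroups
  at $\varepsilon > 0$) is out of scope.
* The null-model template search is exhaustive for transpositions but
  greedy for larger sectors, so it can overestimate a null circuit's best
  achievable epsilon; p-values for `S_k`/`D_1`/`C_k` subgroups are
  therefore optimistic and should be read alongside the exhaustive
  transposition case.
* Polymodal neurons (overlapping sectors, semidirect products) are not
  modeled.
* Chemical and gap-junction circuits are analyzed separately; each
  `circuit` carries a single link type.
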