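---
title: "Predicting mutation-induced stability changes by simulated partial unfolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mutation-induced stability changes by simulated partial unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspgnm)
```

## The model

A folded protein is reduced to its C-alpha trace and treated as an elastic
network: every residue is a bead, and beads interact through Hookean springs.
Backbone neighbours (|i−j| = 1) are always connected; any other pair is
connected when its CA–CA distance is within a cutoff r_c (default 9 Å). The
network is encoded in the Kirchhoff (connectivity) matrix Γ, a weighted graph
Laplacian: off-diagonal entries are minus the spring constant of a connected
pair, diagonal entries make each row sum to zero.

Unlike the classical Gaussian network model, where every spring has unit
stiffness, springs here are weighted by the Miyazawa–Jernigan (MJ)
statistical contact potential: the spring constant of a non-bonded pair with
contact energy MJ_ij (in RT units, all negative) is its Boltzmann weight

    k_ij = exp(−MJ_ij),

so strongly attractive pairs (e.g. Leu–Leu, the table minimum at −7.37 RT)
get stiff springs and fluctuate little, while weak pairs (e.g. Lys–Lys,
−0.12 RT) are loose. Bonded neighbours use exp(−(min(MJ) − 1)), stiffer than
any non-bonded spring, standing in for the covalent backbone.

**Sign convention.** Printed formulations of this spring weighting are
ambiguous about the sign in the exponent. We default to exp(−MJ_ij) because
it is the only choice consistent with the physical requirement that a
residue pair with a stronger (more negative) interaction energy has a lower
mean-squared fluctuation in distance, and with the bonded-spring formula,
which must dominate all non-bonded springs. The literal alternative
exp(+MJ_ij) remains available as `convention = "literal_eq2"` for
sensitivity experiments; all defaults use the negated form.

Residue fluctuations come from the spectrum of Γ. Because rows sum to zero,
Γ is singular (one zero mode per connected component), so its inverse is
reconstructed as a truncated pseudo-inverse over the slowest non-zero modes:

    Γ⁻¹ ≈ Σ_{k=1}^{n_modes} λ_k⁻¹ V_k V_kᵀ,

with eigenvalues in ascending order and the zero mode(s) excluded. The
mean-squared fluctuation (MSF) in the distance between residues i and j —
the internal distance change — is

    MSF_ij = Γ⁻¹_ii + Γ⁻¹_jj − 2 Γ⁻¹_ij.

The physical prefactor 3K_BT/γ is fixed to 1 throughout: no quantity the
method reports depends on it (it rescales all MSFs equally, and the final
ddG is compared to experiment only through correlations and an optional
fitted line). With uniform springs and all modes, MSF_ij is exactly the
effective resistance between nodes i and j of the spring graph, which the
test suite exploits as a closed-form oracle.

## Partial unfolding

Unfolding is simulated as sequential contact breakage. Per iteration:

1. decompose the current Γ; if more than one eigenvalue is (numerically)
   zero the network has fragmented — stop with `termination = "unstable"`;
2. rebuild Γ⁻¹ from the `n_modes` slowest non-zero modes (default 10);
3. over the currently connected non-bonded contacts, find the pair with the
   largest distance MSF, break it (zero the off-diagonal entries and restore
   the row sums), and record the pair with the MSF it broke at;
4. stop once `break_fraction` (default 0.5) of the initial contacts are
   broken.

One contact breaks per iteration, and the eigendecomposition is recomputed
from the updated matrix each time — no low-rank shortcuts. Exact MSF ties,
which occur in symmetric synthetic structures, are broken deterministically
toward the smallest i, then smallest j, so traces are bit-reproducible.
Bonded springs never break and do not count toward the contact total.

Backbone springs keep the contact graph mathematically connected, so
fragmentation manifests numerically: eigenvalues are compared against
`zero_tolerance * max(lambda_max, 1)` with `zero_tolerance = 1e-8`, a
relative threshold that is robust across spring scales. When the tertiary
network of a sparse structure collapses, the spectral gap falls below this
threshold and the run terminates as unstable — the degenerate regime the
50% default stays well away from on compact structures, but which larger
break fractions can reach.

## From broken contacts to ddG

For a wildtype/mutant pair (identical coordinates, one residue type
changed), both networks are partially unfolded. The contacts broken at the
mutation position are ranked 1, 2, ... in break order on each side, and only
ranks present on *both* sides are used (rank matching; the partners need not
be the same residue). With site residue X in the wildtype and Y in the
mutant, and rank-j partners p_j / q_j:

    ddG = −[ Σ_j (MJ(Y, q_j) − MJ(X, p_j)) − Σ_j (MSF_mut,j − MSF_wt,j) ]

The first sum is the enthalpic difference from the contact-energy table; the
second is the entropic proxy. If no contact involving the mutation position
breaks on either side, the prediction defaults to the theoretical value 0
("defaulted_zero") — the local environments of wildtype and mutant are then
indistinguishable to the model.

**Entropy source.** The per-contact MSF entering the entropy term is the
value recorded at the iteration the contact broke (`entropy_from =
"at_break"`), the only per-contact fluctuation the unfolding narrative
produces. An alternative reading evaluates the same residue pairs on the
intact native-state network (`entropy_from = "native"`); both are
implemented, both preserve exact antisymmetry, and at-break is the default.

**Reverse mutations** swap the structures and invert the mutation. When the
mutant model is built in silico the arithmetic is identical with the roles
exchanged, so raw reverse ddG is the exact floating-point negation of the
forward value — antisymmetry of −1 and bias of 0 are identities of the
construction, not fitted outcomes. With an independently solved mutant
structure the traces genuinely differ and antisymmetry becomes an empirical
property.

**Rescaling.** Raw values can be mapped to the experimental scale by a
linear fit (`fit_scaling()`, ordinary least squares of experimental on raw).
The reference coefficients were fitted on a large benchmark whose structures
this package does not redistribute, and are not published; defaults are
slope 1, intercept 0 (raw output), and users with benchmark data can re-fit.
For reverse-direction results the intercept is subtracted rather than added,
which keeps scaled forward/reverse pairs exactly antisymmetric even with a
non-zero intercept.

## Evaluation tools

`read_mutation_table()` ingests CSV benchmarks (PDB id, chain, mutation
token, temperature in °C, pH, experimental ddG in kcal/mol), collecting
malformed rows into a rejects report. `filter_conditions()` applies closed
temperature/pH windows; the default 24–26 °C × pH 6.8–7.2 window is where
most stability measurements cluster and where structure-based predictions
agree best with experiment. Metrics are the Pearson correlation, RMSE with
divisor N, antisymmetry (Pearson between paired forward/reverse
predictions) and the bias score δ = Σ(fwd_i + rev_i)/(2N). The printed form
of the bias score in the method's literature is typographically garbled; the
implementation follows the benchmark-literature convention, the mean of
(forward + reverse)/2. Predictions that defaulted to zero can be included
(as 0) or excluded from metrics via the `zeros` policy of
`parameter_scan()`, mirroring how both reporting styles appear in practice.

## Synthetic fixtures: what they do and do not show

All tests run without downloads on generated structures:

* `ideal_helix` — rise 1.5 Å, radius 2.3 Å, 100° per residue. These
  constants guarantee that |i−j| ∈ {2..5} pairs fall within 9 Å, giving a
  connected, non-trivially weighted network (~3.5 contacts per residue), the
  regime the method assumes.
* `perturbed_helix` — the same with Gaussian coordinate noise (default
  0.3 Å), used where geometric symmetry would otherwise create near-ties.
* `extended` — a straight chain; at 10 Å spacing it has no non-bonded
  contacts at all and exercises the defaulted-zero path.
* `random_compact` — a confined 3.8 Å random walk, for irregular contact
  topologies.

Synthetic B-factors are an affine transform of the uniform-spring network
MSF plus seeded noise, so fluctuation/B-factor agreement has a known
positive sign. Benchmark tables draw temperatures around 25 °C and pH
around 7 with deliberate out-of-range and missing rows.

Everything is reproducible from a single integer seed, and generation
restores the caller's RNG state. Test problem sizes — chains of 10–30
residues, 20 mutation pairs for the antisymmetry/bias checks, 10 fixtures
for brute-force oracle equivalence — were chosen as the smallest networks
that exhibit every behaviour of interest (connected 9 Å networks, rank
mismatches, one-sided emptiness, fragmentation).

Passing on fixtures demonstrates the *identities and contracts* of the
implementation: oracle equivalence of the unfolding trace, exact
antisymmetry and zero bias under structure swap, closed-form fluctuation
limits, determinism. It says nothing about predictive accuracy on real
proteins, which requires curated experimental benchmarks and their PDB
structures; `run_batch()` and `parameter_scan()` are the entry points for
such runs once a user supplies local structure files.

## Numerical choices and degenerate inputs

* Eigendecomposition: full dense symmetric solver; structures of desk-scale
  benchmarks (tens to a few thousand residues) do not need sparse paths.
* `n_modes` larger than the available non-zero modes is capped at N − 1.
* A structure with zero non-bonded contacts yields an empty trace that
  trivially satisfies the stopping rule, and every mutation on it defaults
  to zero rather than erroring.
* Chain breaks: consecutive residues in file order are bonded regardless of
  distance (the bonded spring carries no distance condition); a gap > 4.5 Å
  is logged when `options(pspgnm.verbose = TRUE)`.
* Alternate locations keep the highest-occupancy CA (ties toward altloc
  'A'); duplicated author numbering without altloc codes is an error, not a
  silent merge. Modified residues with a standard parent (MSE, SEP, TPO,
  PTR, CSO, HYP, PCA) are mapped; others are skipped with a logged note.
* Mutations are addressed by author numbering plus insertion code, as
  benchmark tables do; internal indices are never exposed.

## Limitations

Single amino-acid substitutions only; one chain per run (inter-chain
contacts are outside the model); C-alpha resolution with no side-chain
geometry, so a mutation changes spring stiffnesses but never coordinates;
experimental temperature and pH are used only to stratify evaluation, not to
reweight interactions. Thermal and chemical denaturation data are treated
alike.
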