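# pspgnm

Structure-based prediction of the stability change (ΔΔG, kcal/mol) caused by
a single point mutation, for structural biologists and method developers who
want an unsupervised, physics-flavoured baseline that runs from a PDB file
alone — no training, no side-chain modelling.

## The method

A protein is coarse-grained to its C-alpha trace and modelled as a Gaussian
network: residues within r_c = 9 Å interact through Hookean springs, encoded
in the Kirchhoff matrix Γ (off-diagonals −k_ij, rows summing to zero).
Springs are weighted by the Miyazawa–Jernigan contact potential (AAindex
MIYS960101, shipped with the package): a non-bonded pair with contact energy
MJ_ij gets stiffness exp(−MJ_ij), and backbone neighbours get the dominant
spring exp(−(min MJ − 1)). Fluctuations come from the truncated pseudo-inverse
over the N_modes = 10 slowest non-zero modes,

    Γ⁻¹ ≈ Σ_k λ_k⁻¹ V_k V_kᵀ,    MSF_ij = Γ⁻¹_ii + Γ⁻¹_jj − 2Γ⁻¹_ij.

Partial unfolding breaks, one per iteration, the non-bonded contact with the
largest distance MSF, until 50% of the native contacts are gone (or the
network fragments). For a wildtype/mutant pair, the contacts broken at the
mutation site are ranked in break order on each side and matched by rank;
with site residue X (wildtype) / Y (mutant) and rank-j partners p_j / q_j:

    ΔΔG = −[ Σ_j (MJ(Y, q_j) − MJ(X, p_j)) − Σ_j (MSF_mut,j − MSF_wt,j) ]

If no site contact breaks on either side the prediction defaults to 0.
Reverse mutations swap the two structures, which makes forward/reverse
predictions exactly antisymmetric by construction. Evaluation helpers
provide Pearson correlation, RMSE, antisymmetry and the bias score
δ = Σ(fwd+rev)/(2N), plus temperature/pH condition filters and (r_c, N_modes)
parameter scans. See `vignettes/psp-gnm-methods.Rmd` for assumptions,
parameter rationale and limitations.

## Worked example

Everything below runs on synthetic fixtures — no downloads.

```r
library(pspgnm)

pair <- make_mutant_pair(n_residues = 25, seed = 3)  # helical wildtype + V8C mutant
pair$spec
#> Mutation V8C (chain A)

fwd <- compute_ddg(pair$wt, pair$spec, mj_potential())
rev <- compute_reverse_ddg(pair$wt, pair$spec, mj_potential())
fwd
#> ddG V8C [forward]: raw = -0.9100, scaled = -0.9100 (computed, N = 4)
rev
#> ddG C8V [reverse]: raw = 0.9100, scaled = 0.9100 (computed, N = 4)
```

The forward prediction is negative (destabilizing valine-to-cysteine swap in
this synthetic helix) and the reverse value is its exact negation; `N = 4`
rank-matched contacts at position 8 contributed. The unfolding trace behind
it:

```r
tr <- unfold(pair$wt, mj_potential())
tr
#> Unfolding trace for SYN0003 chain A
#>   43 of 86 contacts broken; termination: reached_fraction
head(broken_contacts_at(tr, which(pair$wt$resno == pair$spec$position)), 3)
#>   rank partner_index partner_restype msf_at_break
#> 1    1            13               G 0.0007385372
#> 2    2            12               G 0.0007215198
#> 3    3             3               E 0.0007826877
```

For real structures, point the same functions at PDB files
(`parse_calpha()`, `run_single()`, `run_batch()`), or use the CLI:

```sh
exec/psp-gnm run --pdb WT.pdb --chain A --mutation D89E --out result.tsv
exec/psp-gnm batch --table mutations.csv --pdb-dir structures/ --out pred.tsv
```

Benchmark tables are plain CSV with header
`pdb_id,chain,mutation,temperature,ph,exp_ddg[,direction]`. The package does
not redistribute or download benchmark structures.

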