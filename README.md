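# specswitch

Structure-based design of **complex-specificity switch mutations**: given a
protein that is the shared subunit of two mutually exclusive complexes (the
canonical example is the yeast Tor2 kinase, shared between TORC1, defined by
its partner Kog1, and TORC2, defined by Avo3), `specswitch` finds the
residues that bind one complex-specific partner but none of the other
complex's subunits, and proposes mutations intended to abolish the one
complex state while preserving the other.

## Method

For the shared subunit S with partners P⁺ (to be displaced) and P⁻ (to be
kept), modelled in complexes M₁ = (S, P⁺) and M₂ = (S, P⁻):

* **Template-based complex modelling.** Each subunit sequence is aligned to
  its template chain (Needleman–Wunsch, BLOSUM62, affine gaps 11/1) and
  threaded onto the template backbone (identical residues keep side chains,
  mismatches are CB-truncated). Chains are placed by Kabsch (SVD)
  superposition on CA anchors and residual van der Waals overlap
  Σ max(0, rᵢ + rⱼ − d)² is relieved by small rigid shifts.
* **Differential interface.** Residue i of S is selected iff
  min heavy-atom distance d(i, P⁺) ≤ c in M₁ and
  d(i, X) > c + m for every subunit X of the other complex state,
  with contact cutoff c = 4.5 Å and exclusion margin m = 1.5 Å by default.
* **Partner-unique loops.** Regions of P⁺ present in the reference species
  but gapped in all orthologues of a supplied MSA flag the differential
  residues that contact them.
* **Mutation rules.** Hydrophobic → Gln (larger, hydrophilic, uncharged);
  Lys → Arg and Asp → Glu (larger, same charge); everything else flagged
  for manual review. Each proposal is scored for steric clash against P⁺
  over a fixed 27-rotamer chi library and checked for solvent exposure
  (relative SASA of S alone ≥ 0.2, Shrake–Rupley, Gly-X-Gly maxima).
* **Combinations.** Targets are grouped (sequence windows by default) and
  all 2^g − 1 non-empty group unions are enumerated as the named mutant
  series K1, K2, K3, K12, K13, K23, K123, ...

A synthetic fixture generator builds toy helical complexes with known
ground-truth interfaces so the entire pipeline is testable offline; see the
vignette (`vignettes/specificity-switch-design.Rmd`) for the model,
parameters and limitations.

## Worked example

A fixture where partner B touches focal residues 10–24 and partner C touches
20–39, so the true differential interface is 10–19:

```r
library(specswitch)
ds <- run_design(list(fixture = list(interval_1 = c(10, 25),
                                     interval_2 = c(20, 40))))
ds
#> <sw_design_set> ok
#>   target region 10..19, 10 proposals, 1 groups, 1 combinations
#>    A10Q A11Q A12Q A13Q A14Q A15Q A16Q A17Q A18Q A19Q
subset(ds$proposals, selected,
       select = c(position, wt_aa, mutant_aa, rule, clash_max, exposed))
#>    position wt_aa mutant_aa               rule clash_max exposed
#> 1        10     A         Q hydrophobic_to_gln  25.07303    TRUE
#> 2        11     A         Q hydrophobic_to_gln  26.56653    TRUE
#> ...
#> 10       19     A         Q hydrophobic_to_gln  26.72108    TRUE
```

Every selected residue is in the constructed truth set 10..19; the poly-Ala
fixture makes each proposal follow the hydrophobic rule (A→Q), each site is
solvent-exposed on the free subunit, and each glutamine can clash with the
displaced partner (`clash_max` > 0, in Å² soft-sphere overlap units). On a
single-residue scale:

```r
propose_mutation(775, "A")
#>   position wt_aa mutant_aa               rule notes
#> 1      775     A         Q hydrophobic_to_gln
```

Real systems are run from a YAML config naming the two template structures
(PDB/mmCIF), the chain roles, target sequences and optional orthologue MSA:

```yaml
complexes:
  model_1: {template: torc1_template.pdb, shared: A, included: K}
  model_2: {template: torc2_template.cif, shared: A, specific: V}
sequences: {A: tor2.fasta, K: kog1.fasta, V: avo3.fasta}
cutoff: 4.5
exclusion_margin: 1.5
```

and `spec-switch run --config run.yaml` (the CLI lives in
`inst/cli/spec-switch.R`), or `run_design("run.yaml")` from R.

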