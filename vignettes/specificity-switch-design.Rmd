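---
title: "Designing complex-specificity switch mutations from structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing complex-specificity switch mutations from structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specswitch)
```

## The problem

Some proteins assemble into more than one mutually exclusive complex. The
motivating case is the yeast Tor kinase system: the Tor2 kinase is the shared
subunit of two complexes, TORC1 (where it binds the partner Kog1) and TORC2
(where it binds Avo3), and the two complexes have distinct signalling roles.
To dissect the biology of one complex without touching the other, one wants a
*specificity switch*: a small set of mutations on the shared subunit that
abolishes assembly of one complex state while preserving the other.

`specswitch` implements the structure-based design procedure for such
switches as a reusable pipeline:

1. **Model both complex states.** Each subunit sequence is threaded onto a
   template complex structure (alignment-guided coordinate grafting), the
   grafted chains are superposed onto their template positions (Kabsch), and
   residual inter-chain van der Waals overlap is relieved by small rigid
   shifts.
2. **Find the differential interface.** Residues of the shared subunit that
   contact the partner to be displaced (heavy-atom minimum distance at or
   below a cutoff) in one model, while keeping a safety margin of clearance
   from *every* subunit of the other complex state.
3. **Annotate partner-unique loops.** If an orthologue alignment of the
   included partner is supplied, differential residues whose contacts fall in
   regions present only in the reference species are flagged: contacts
   against such species-specific loops are the most promising handles,
   because the loop's presence suggests it contributes to assembly in this
   species specifically.
4. **Propose mutations.** Hydrophobic residues become glutamine — larger
   than the typical interface hydrophobic, and hydrophilic but uncharged, so
   the surface left exposed when the complex no longer forms stays benign.
   Charged residues become the larger residue of the same charge (Lys to
   Arg, Asp to Glu), preserving electrostatics while adding bulk. Residues
   with no prescribed rule (polar-uncharged; Gly/Pro/Cys/His; Arg and Glu,
   which have no larger same-charge option) are flagged for manual review
   rather than silently substituted.
5. **Check each proposal geometrically.** A small fixed rotamer library of
   the mutant side chain is built on the model backbone and scored against
   the displaced partner with a soft-sphere overlap; the residue's solvent
   exposure is checked on the shared subunit alone, the state the surface
   would face once the complex is lost.
6. **Group and enumerate.** Targets are grouped (by sequence windows,
   spatial clustering, or an explicit partition) and all non-empty unions of
   groups are enumerated as named mutant combinations (`K1`, `K2`, `K12`,
   ..., `K123`), which is the granularity at which such designs are
   validated experimentally.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 4.5 Å | heavy-atom minimum distance defining a residue contact |
| `exclusion_margin` | 1.5 Å | extra clearance beyond `cutoff` required to call a residue free of an excluded partner |
| `exposure_threshold` | 0.2 | minimum relative SASA (residue SASA / Gly-X-Gly maximum) to call a site exposed |
| `probe_radius` | 1.4 Å | water probe for Shrake–Rupley SASA |
| `n_points` | 960 | sphere quadrature points per atom |
| `chi_values` | −60°, 60°, 180° | chi library per rotatable bond, capped at 27 rotamers |
| grouping `window_len` | 10 | sequence gap that separates mutation groups |

The contact cutoff is the conventional heavy-atom interface definition;
because no single value is privileged, it is exposed in the config, and
analyses of real systems should sweep it (4.0–5.0 Å is a reasonable range).
The exclusion margin exists because grafted models are approximate: "does
not bind the other partner" is asserted only with 1.5 Å of slack beyond the
contact cutoff. The rotamer library is for *clash coverage*, not energy
ranking — the question is whether some rotamer of the designed side chain
must collide with the partner, not which rotamer is most stable.

## Numerical choices

* **Author numbering is the public residue identifier** end-to-end, because
  design targets are communicated as author-numbered labels (e.g. A775).
  Grafted chains are numbered by target sequence position.
* **Altloc resolution** keeps the highest-occupancy conformer, ties broken
  by altloc letter; hydrogens are dropped on read (all kernels are
  heavy-atom based); first model only.
* **Alignment** is Needleman–Wunsch with affine gaps (BLOSUM62, gap open 11,
  extend 1; gap of length L costs `open + L·extend`, end gaps included).
  Percent identity is reported under three conventions (identical /
  aligned pairs, / columns, / shorter sequence) because published identity
  values rarely state their denominator.
* **Kabsch superposition** anchors CA atoms only, making the fit robust to
  side-chain differences between model and template; the SVD determinant
  correction guarantees a proper rotation.
* **Clash relief** translates one chain along the axis between the two
  sides' interface centroids in 0.25 Å steps, accepting a step only if the
  soft-sphere overlap does not increase; the overlap score is
  `sum(max(0, r_i + r_j − d)²)` over inter-chain heavy-atom pairs, zero
  exactly when nothing interpenetrates.
* **Grafting** copies template backbone coordinates; identical residues keep
  the template side chain, mismatches are truncated to N, CA, C, O, CB (CB
  rebuilt at ideal tetrahedral geometry, CA–CB 1.53 Å) rather than given
  invented rotamers. Unaligned target residues are reported as unmodelled,
  never built — no loop modelling, no minimisation. This is sufficient for
  interface *identification*, which is a backbone-proximity question.
* **SASA** uses a fixed embedded van der Waals radius table (Bondi-type:
  C 1.70, N 1.55, O 1.52, S 1.80 Å, ...) and a deterministic golden-spiral
  quadrature, so values are bit-reproducible. At 960 points the quadrature
  error of an isolated atom is below 1% of the closed form
  `4π(r + probe)²`.
* **Exposure** is normalised by the Gly-X-Gly theoretical maxima (Tien et
  al. 2013) of the residue type present in the model: the measured quantity
  is how exposed the *site* is, so the wild-type residue and its own
  reference maximum are used.
* **Unique regions** are maximal runs of alignment columns where the
  reference row has residues and every orthologue row has a gap; runs
  shorter than 3 reference residues are treated as alignment noise.

## Design decisions that were genuinely open

* The mutation rules only prescribe substitutions for hydrophobic and
  charged residues. The classification table used here is
  hydrophobic = {A,V,L,I,M,F,W,Y}, positive = {K,R}, negative = {D,E},
  polar-uncharged = {S,T,N,Q}, special = {G,P,C,H}. His is "special"
  because its charge is pH-dependent; Trp/Tyr follow the hydrophobic rule
  but their proposals carry an "aggressive" note, since removing a large
  aromatic is a bigger perturbation than the rule anticipates.
* `run_design` filters proposals on exposure by default but records the
  clash score without filtering on it (`require_clash = FALSE`): a
  CB-truncated model cannot prove the *absence* of a designed clash, so
  treating "no predicted clash" as disqualifying would discard valid sites
  for a model-quality reason. Both switches are config keys.
* The grouping of targets into named clusters is not derivable from
  first principles; the default sequence-window heuristic (gap > 10
  residues starts a new group) reproduces the natural three-cluster
  structure of targets such as {740, 742}, {768..781}, {817, 818}, and an
  explicit partition can always be supplied.
* Side chains are built by internal-coordinate (NeRF) placement with ideal
  bond lengths and angles; aromatic rings are placed by fixed torsions and
  are approximate (ring closure is not enforced), which is adequate for
  overlap scoring.

## The synthetic fixture generator

`make_two_partner_fixture()` builds a focal ideal α-helix (φ = −57°,
ψ = −47°, ideal backbone geometry, CB on every non-Gly residue) and two
partner chains whose contact footprints on the focal chain are *known
half-open residue intervals*. Partner pseudo-atoms are planted on the radial
through each interval residue's CB at 3.8 Å (a typical heavy-atom contact
distance), with two flankers slightly inside the approach distance so each
planted contact is redundant under coordinate noise. By construction every
non-interval residue stays > 6.4 Å from any partner atom — beyond
`cutoff + exclusion_margin` — so the ground-truth interface, differential
set and mutation list are exact, derived from the construction rather than
re-measured. `perturb()` adds seeded i.i.d. Gaussian coordinate noise for
robustness tests.

What the fixtures deliberately do **not** emulate: folded tertiary
structure, realistic side-chain packing, partner chains with real backbones,
binding-energy contributions, or conformational change on binding. Passing
the fixture suite therefore demonstrates that the geometric machinery
(contacts, mapping, set logic, rules, enumeration) is exact, not that
grafted models of real complexes are accurate — on real systems the
dominant error is the template-based model itself, which is why the cutoff
sweep and the exclusion margin exist.

Test problem sizes were chosen to keep the suite fast while still exercising
every code path: 60-residue focal helices, 100-atom-per-chain random clouds
for the contact oracle (100 seeds), 50 interval configurations for
end-to-end recovery, and 20 noisy replicates at σ = 0.3 Å.

## A worked fixture example

```{r}
ds <- run_design(list(fixture = list(interval_1 = c(10, 25),
                                     interval_2 = c(20, 40))))
ds
subset(ds$proposals, selected,
       select = c(position, wt_aa, mutant_aa, rule, clash_max, exposed))
```

Partner 1 touches focal residues 10–24, partner 2 touches 20–39, so the
differential interface is exactly residues 10–19; on the poly-Ala fixture
every proposal follows the hydrophobic rule (A→Q). With a single contiguous
group there is one combination, `K1`.

## Known limitations

* No side-chain repacking or energy model: the clash score is a geometric
  screen, not a ΔΔG.
* No prediction of fold stability or expression level of the mutants — a
  combination that satisfies every geometric criterion can still destabilise
  the protein.
* Template-based grafting inherits template conformations; conformational
  differences between species or complex states beyond rigid-body placement
  are invisible.
* Assembly clash relief is rigid-body and per-chain; it cannot resolve
  interpenetration that requires backbone rearrangement.
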