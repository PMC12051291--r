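---
title: "Structural context of PTM sites and evaluation of modelled ligand poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural context of PTM sites and evaluation of modelled ligand poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmligand)
```

## The problem

Post-translational modifications (PTMs) such as phosphorylation or
acetylation can change how a protein binds a small molecule. A first-order
structural screen for such effects asks a geometric question: does the
modified residue sit close to the bound ligand? A second question follows for
predicted structures: when a model of the (possibly PTM-modified) protein is
produced, does it place the ligand where the experimental structure does, and
does it preserve the protein-ligand contact network?

`ptmligand` implements both halves as a tested pipeline:

1. **Annotation** — map PTM sites given in reference-sequence (UniProt-style)
   numbering onto the residues of a deposited structure, and report every
   site whose residue lies within a distance cutoff of any ligand atom,
   optionally assigned to domain ranges.
2. **Evaluation** — superpose a model onto the reference complex with a
   sequence-guided, outlier-rejecting rigid fit, then score the ligand pose
   by no-fit RMSD and the interface by an lDDT-PLI contact-conservation
   score.

## Annotation model

PTM tables (dbPTM-like TSV: accession, position, residue, PTM type) are
deduplicated per (accession, position, PTM type) and validated against the
reference sequence: a site is usable only when the sequence actually carries
the stated residue at the stated position. Mismatching or out-of-range rows
are flagged (`residue_mismatch`, `unmapped`), reported, and excluded from the
geometry — never silently dropped. This mirrors the curation reality that
site tables and sequence versions drift apart.

Structure residues are renumbered onto the reference sequence by global
Needleman–Wunsch alignment (BLOSUM62, affine gaps 11/1). Chains whose
alignment identity falls below a floor (default 0.30) are rejected outright;
this is the package's guard against chimeric chains or a wrong reference
sequence. Residue-level identity is tracked per position, and an unknown
residue type (`X`) never counts as identical.

A site is **proximal** when the minimum distance between any heavy atom of
its residue and any heavy atom of the ligand instance is at most the cutoff
(default 10 Å, boundary inclusive). Two conventions deserve note:

* *Whole-residue measurement.* The modified atom itself is not, in general,
  resolvable from a site table, so the most inclusive defensible reading —
  any atom of the modified residue — is the default. The cutoff is a plain
  argument, so stricter conventions are one call away.
* *Inclusive boundary.* A site at exactly the cutoff is included.

Proximity uses a cell-list spatial grid with cells of cutoff size, which is
exact for all distances at or below the cutoff; its contract (and its test
oracle) is the all-pairs distance scan.

## Superposition

Models are superposed on the reference by the classical sequence-guided
scheme: per-chain global alignment establishes residue pairs, atoms are then
paired by identical name within a scope (all heavy atoms by default;
backbone or CA-only available), and a least-squares rigid fit (Kabsch, SVD
with reflection correction) is computed. Up to five refinement cycles
follow; in each cycle atom pairs whose deviation exceeds the mean plus two
standard deviations of the current deviations are rejected and the fit is
repeated. Refinement stops early when a cycle rejects nothing or when fewer
than a minimum number of pairs (default 10) would remain.

Numerical choices:

* Rejection applies to atom *pairs*, not whole residues.
* Deviations are centred at the mean of the retained pairs, and a pair must
  additionally deviate by more than 1e-6 Å to be rejected, so an exact rigid
  copy never sheds pairs to floating-point noise.
* Tie-breaking in the alignment traceback follows the alignment engine's
  deterministic rule; scores are invariant to it.
* The rotation is checked proper (det = +1); near-collinear atom sets are
  flagged as degenerate.

When domain orientations differ between model and reference (hinge motions),
the correspondence can be restricted to ECOD-style ranges
(`restrict_to`/`--restrict`, e.g. `"A:1-120"`) so only the binding domain
drives the fit. The package does not auto-detect hinges; the whole-structure
and restricted RMSDs are both available to inform that judgement.

## Ligand RMSD

After superposition, the ligand pose error is the root mean squared
coordinate difference over atoms paired strictly by name, with **no
refitting** (`rmsd_no_fit`). Predicted models often rename ligand atoms while
preserving the component file's atom order; `harmonize_atom_names` renames
positionally against an SDF or CCD component file, refusing on any count or
element mismatch rather than guessing a partial mapping. When a component
carries several copies in either structure, every model-copy x
reference-copy combination is reported and the minimum per model copy is
flagged `best`, since the correct copy pairing is not knowable in general.

Symmetry-equivalent atom namings (ring automorphisms) are deliberately not
canonicalized: pairing is strictly by name/order, which over-estimates the
RMSD of symmetric ligands. A symmetry-corrected RMSD is out of scope and
should be borne in mind when interpreting large values for symmetric
compounds.

## lDDT-PLI

Interface atoms are selected on the **reference only**: protein atoms within
5 Å of any ligand atom, plus ligand atoms within 5 Å of any protein atom
(inclusive). For every unordered pair of interface atoms, the absolute
difference Δd between the reference and model inter-atom distances is scored

| Δd (Å)        | f    |
|---------------|------|
| < 0.5         | 1    |
| 0.5 – 1.0     | 0.8  |
| 1.0 – 2.0     | 0.6  |
| 2.0 – 4.0     | 0.4  |
| ≥ 4.0         | 0    |

with lower bounds inclusive. Each atom averages f over its pairs, and the
score averages over the N interface atoms. Distances are internal, so the
score needs no superposition and is invariant to rigid motions of the model
to machine precision.

Two deliberate divergences from CASP-style lDDT: there is no inner inclusion
radius for neighbour pairs beyond interface membership (every pair of
interface atoms is scored, protein-protein pairs included — a
`include_intra = FALSE` mode restricts to protein-ligand contacts), and no
stereochemical checks are performed. Atoms of the reference interface that
lack a model correspondent are an error under the default strict mode;
lenient mode drops them with a reported count.

## The synthetic-data generator

All tests run on generated fixtures with analytically known answers; nothing
is downloaded. `make_toy_complex` builds an idealized helical chain (2.3 Å
radius, 1.5 Å rise, 100°/residue, five placeholder heavy atoms per residue)
with a short hetero-chain ligand placed 40 Å away, so that by construction
only deliberately placed residues are anywhere near it. Three kinds of
residues are relocated next to the ligand:

* **planted PTM sites**, whose nearest-atom distance to the ligand is
  realized *exactly* (the site's CB is placed at the requested distance from
  the nearest ligand atom along a direction that keeps every other atom
  strictly farther) — defaults are one site at 8 Å and one at 12 Å,
  bracketing the 10 Å cutoff;
* **pocket residues** at 3.0–4.5 Å, so the complex has a genuine 5 Å
  interface for lDDT-PLI;
* optional **invalid table rows** (wrong residue letter, out-of-range
  position) for exclusion-bookkeeping tests.

`make_model_variant` derives models by known perturbations: `rigid` (exact
post-superposition ligand RMSD 0), `ligand_shift(d)` (exact RMSD d),
`jitter(σ)` (i.i.d. coordinate noise on the ligand atoms; expected squared
RMSD 3σ²), `hinge(angle, pivot)` and `residue_kick(index, d)`. Jitter is
applied to the ligand only so the protein superposition stays exact and the
3σ² expectation is clean — it emulates pose uncertainty, not fold
uncertainty. Every expectation is written to a JSON manifest and the test
suite recovers each one from the pipeline output.

What the fixtures do **not** emulate: real rotamer geometry, occupancy and
altloc quirks of crystal structures, correlated model errors, or the format
idiosyncrasies of specific prediction tools. Passing tests therefore
demonstrate the correctness of the geometry, scoring and bookkeeping — not
robustness to every real-world file.

Typical problem sizes in the test suite are 20–60 residues and 8 ligand
atoms, with 20-seed replicates where sampling distributions are checked
(e.g. mean squared jitter deviation within 20% of 3σ², a ±3 SD band at these
sizes); these sizes keep the full suite under a minute while leaving the
sampling checks well-powered.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `proximity_cutoff` | 10 Å | PTM residue-to-ligand minimum distance |
| `interface_cutoff` | 5 Å | interface atom selection |
| `max_cycles` | 5 | superposition refinement cycles |
| `sd_cutoff` | 2.0 | outlier rejection threshold (SDs above the mean) |
| `scope` | `"heavy"` | atoms used for correspondence |
| `identity_floor` | 0.30 | minimum chain alignment identity |
| `min_pairs` | 10 | minimum retained atom pairs in refinement |
| gap penalties | 11 / 1 | affine gap open/extend with BLOSUM62 |

## Known limitations

* No symmetry-corrected ligand RMSD; symmetric ligands over-estimate.
* No automatic hinge/domain-motion detection; restriction is manual.
* The renumbering aligner is a global aligner, chosen as the cleaner
  contract for single-protein chains; heuristic local tools used in
  large-scale database work may map extreme edge cases differently.
* mmCIF support covers atom-site needs (plus CCD component atom tables);
  assemblies, maps and entity bookkeeping beyond that are out of scope.

## A worked run

```{r example, eval = FALSE}
fx <- make_toy_complex(fixture_spec(seed = 1), dir = tempfile())
mv <- make_model_variant(fx$structure,
                         list(type = "ligand_shift", d = 5), seed = 2)
res <- run_compare(fx$paths$reference_pdb, mv$paths$model_pdb, "LIG")
res$ligand_rmsd
res$lddt_pli
```
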