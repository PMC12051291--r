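# ptmligand

Structural-context analysis of post-translational modification (PTM) sites
around bound small molecules, and evaluation of modelled ligand poses against
reference complexes.

## Who this is for

Structural bioinformaticians who (a) have a protein–ligand complex and a
table of PTM sites in reference-sequence (UniProt-style) numbering and want
to know which modifications sit in or near the binding site, and (b) have
predicted models of the same complex — e.g. from structure-prediction or
docking tools, possibly PTM-modified — and want quantitative agreement
measures against the experimental pose.

## What it computes

**Binding-site-proximal PTMs.** Chain residues are renumbered onto the
reference sequence by global Needleman–Wunsch alignment (BLOSUM62, affine
gaps 11/1; chains below 30% identity are rejected as probable chimeras).
Sites whose stated residue type disagrees with the sequence are flagged and
excluded with full bookkeeping. A site is proximal when

    min over (residue heavy atom a, ligand heavy atom b) of |a − b| ≤ 10 Å

(boundary inclusive, cutoff configurable), computed with a grid search whose
contract is the exact all-pairs scan. Sites map onto ECOD-style domain
ranges (`"A:12-150,A:200-240"`).

**Superposition.** Sequence-guided rigid-body fit (Kabsch) with up to five
cycles of iterative refinement; per cycle, atom pairs deviating more than
two standard deviations above the mean deviation are rejected and the fit
repeated. The correspondence can be restricted to the binding domain when
domain orientations differ.

**No-fit ligand RMSD.** After superposition, `rmsd = sqrt(mean(|a_i − b_i|²))`
over atoms paired strictly by name, with no refitting. Model ligand atoms
with nonstandard names are renamed positionally against an SDF/CCD component
file. Multiple copies yield per-copy reports with a best-match flag.

**lDDT-PLI.** Interface atoms are reference protein/ligand atoms within 5 Å
of the binding partner. For every unordered interface-atom pair, the absolute
distance difference Δd = |d_pred − d_ref| is scored

    f(Δd) = 1 (Δd < 0.5 Å), 0.8 (0.5–1), 0.6 (1–2), 0.4 (2–4), 0 (≥ 4 Å)

and lDDT-PLI = (1/N) Σ_i (1/M_i) Σ_j f(Δd_ij) — per-atom means averaged over
the N interface atoms. Superposition-free and rigid-motion invariant.

A synthetic-fixture generator (`make_toy_complex`, `make_model_variant`)
builds complexes with *exactly* planted proximity distances, ligand shifts,
coordinate noise, hinge motions and displaced residues, each with a JSON
manifest of analytic expectations; the test suite recovers every one.

## Worked example

```r
library(ptmligand)

fx <- make_toy_complex(fixture_spec(seed = 1), dir = tempfile())
run_annotate(fx$paths$reference_pdb, fx$paths$ptm_tsv,
             fx$paths$sequence_fasta, domains = fx$paths$domain_tsv,
             out = "proximal.tsv")
read.delim("proximal.tsv")
#>   accession position residue        ptm_type comp_id lig_chain lig_resno chain
#> 1     SYNP1       12       S Phosphorylation     LIG         A       161     A
#>   resno insert min_distance domain_id
#> 1    12     NA     8.000206        D1
```

The fixture plants two phosphosites, at 8 Å and 12 Å from the ligand; only
the 8 Å site passes the 10 Å cutoff (the 2e-4 Å excess is PDB coordinate
precision), lands on chain residue 12 and falls in domain D1.

```r
mv  <- make_model_variant(fx$structure, list(type = "ligand_shift", d = 5),
                          seed = 2)
res <- run_compare(fx$paths$reference_pdb, mv$paths$model_pdb, "LIG")
res$superposition
#> SuperpositionResult: 300/300 atom pairs retained over 0 cycle(s), final RMSD 0.0000 A
res$ligand_rmsd
#>   comp_id model_copy reference_copy n_atoms     rmsd harmonization best
#> 1     LIG       A161           A161       8 4.999939  name-matched TRUE
res$lddt_pli
#> InterfaceScore (lDDT-PLI): 0.8278 over 9 interface atoms (36 pairs)
```

The model's protein is identical to the reference, so the superposition
keeps all 300 atom pairs at RMSD 0; the ligand was shifted by exactly 5 Å,
and the no-fit ligand RMSD recovers it to file precision. The interface
score drops below 1 because every protein–ligand contact distance changed by
the shift, while protein–protein interface distances are preserved.

A thin command-line wrapper is installed with the package
(`inst/cli/ptmligand.R`; subcommands `simulate`, `annotate`, `compare`,
`superpose`, `score-lddt`).

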