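---
title: "Methods: template-anchored CDR3 mutation pathways and interface analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-anchored CDR3 mutation pathways and interface analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

T-cell receptors (TCRs) recognize peptides presented by MHC molecules
mostly through their hypervariable CDR3 loops. Solved TCR-peptide-MHC
complex structures are scarce compared with the number of TCR sequences of
known specificity, but many database sequences differ from a solved
structure's CDR3 by only one to three substitutions, and such nearby
variants rarely change specificity. `tcrpmhc` turns that observation into
a pipeline: anchor a cluster of specificity records at a solved template's
CDR3 ("core"), enumerate stepwise single-substitution pathways out to the
cluster edge, build a model per step, and analyze how the substitutions
change CDR3-peptide contacts and interface energies.

## Clustering and mutation pathways

A record joins a core's cluster when it matches the core's chain, V gene,
J gene, epitope and CDR3 length (no insertions or deletions), lies within
Hamming distance 3 of the core, and is reachable from the core through
single-substitution steps. Two reachability modes are offered:

* **observed** (default): every intermediate must itself be an observed
  record. This reads the accretion rule strictly - clusters grow by
  attaching sequences one substitution away from a sequence already in the
  cluster - and means an isolated distance-2 record without a recorded
  intermediate is excluded.
* **free**: intermediates may be unobserved sequences; any record within
  distance 3 joins. This is the permissive reading; it is behind a flag
  because it manufactures intermediate structures no database entry
  supports.

Pathways are restricted to distance-monotone chains: each step is a single
substitution and the Hamming distance from the core increases by exactly
one per step. Revisiting a position, or stepping sideways at constant
distance, is disallowed; with at most three total substitutions such
detours would only produce chains longer than the member's distance, which
the three-step budget rules out. A member can still be reached through
several orders of its substituted positions, which is exactly how the same
final CDR3 yields multiple models. Build orders are deduplicated on the
pathway prefix so shared prefixes are built once, and both counters (full
pathways, deduplicated build orders) are reported, since "number of
pathways" is ambiguous between the two.

TCR alpha and beta chains are clustered independently; chain pairing is
not modeled. V/J equality is compared on the full allele-resolved string
by default, with a flag to compare at gene level (allele suffix stripped),
because public database entries vary in allele resolution.

Members and pathways are emitted in lexicographic order, making all
outputs deterministic.

## Model building

The mutation step retains every main-chain heavy atom (and the beta
carbon, when the target is not glycine) from the parent and rebuilds the
remaining side-chain atoms from an internal ideal-geometry table using the
natural-extension reference frame, copying side-chain torsions from the
parent wherever the defining atom names coincide. Mutating a residue to
its own type is the identity. The builder is deterministic, so repeated
runs are bitwise identical.

This *surrogate backend* deliberately does not reproduce a molecular
mechanics program. It exists so that every downstream stage - contact
detection, energy differencing, statistics - runs and is testable offline.
The backend contract (`mutate`, `optimize`) accepts external tools: a
wrapper around a Rosetta-style mutation/minimization protocol (mutate with
fixed main chain; L-BFGS minimization under C-alpha coordinate restraints
with a 0.5 A deviation cap; side-chain repacking for CDR3/peptide residues
within 10 A of each other) plugs in without touching the analyses, and
precomputed per-model energy tables can be loaded directly with
`read_energy_table()`.

Two optimization arms are kept throughout because the analyses compare
them: for the surrogate, "minimized" is a no-op (an ideal-geometry build
under tight coordinate restraints has nothing to minimize) and "repacked"
runs a greedy chi1 grid search (steps of 60 degrees) that relieves
side-chain clashes for CDR3/peptide residues within 10 A of each other,
accepting a rotamer only when it lowers the full-preset interface energy.
Ring residues are built as dihedral chains, so rings close only
approximately; this is acceptable for a distance-based surrogate and is
invisible to the contact rules, which use atom positions, not ring
topology.

Models sharing the template's full set of TCR chain sequences, the final
CDR3 and the chain form one *non-redundant group*; group-averaged rates
are reported next to raw ones wherever both are meaningful, since
different PDB entries can carry identical TCR chains.

## Contacts

A contact pair is a (CDR3 residue, peptide residue) pair with minimum
heavy-atom distance below 5 A. Hydrogens are ignored even if present:
crystal structures usually lack them and the interaction-network rules
operate on heavy atoms. Parts (main chain / side chain) are attributed
from the atom pair achieving the minimum distance; a config option can
switch to any-pair attribution for sensitivity analysis. Typing follows
residue-interaction-network-style thresholds with precedence IONIC >
HBOND > VDW:

* **IONIC**: oppositely charged side-chain group atoms (Asp/Glu
  carboxylate versus Lys NZ / Arg guanidinium / His ring nitrogens)
  within 4.0 A;
* **HBOND**: donor and acceptor heavy atoms within 3.5 A (no angle term,
  as no hydrogens are placed);
* **VDW**: everything else under the 5 A cutoff.

Per contacting CDR3 residue exactly one pair carries the closest-contact
flag; ties break toward the lower peptide position. Four analysis groups
are derived: all pairs; closest pairs; pairs with at least one side-chain
part; and the intersection of the last two. Side-chain contacts matter
most because side chains carry nearly all residue-specific chemistry.

## Interface energies

Energies are computed over CDR3-peptide atom pairs only (face 1 = CDR3,
face 2 = peptide) and decomposed per CDR3 residue; each pairwise term is
assigned wholly to the CDR3-side residue, so contributions sum exactly to
the total. Three presets mirror the term taxonomy the analyses compare:

| preset | terms |
|---|---|
| `large_patch` | fa_atr, fa_sol, hbond_sr_bb, hbond_lr_bb, hbond_bb_sc, hbond_sc |
| `small_patch` | large_patch minus hbond_sr_bb and hbond_bb_sc |
| `full` | large_patch plus the clash term fa_rep |

Surrogate term forms (constants configurable): fa_atr is the attractive
Lennard-Jones branch with per-element radii, clamped at the contact radius
and cut at 6 A; fa_rep is the repulsive branch inside the contact radius;
fa_sol is a burial penalty of +0.2 per polar-polar atom pair within
4.5 A; hydrogen bonds score -1.5 times a cosine switch between 2.6 and
3.5 A on donor/acceptor heavy-atom pairs, classified into the four
backbone/side-chain classes by the backbone flags of donor and acceptor.
Because the short/long-range backbone split is a sequence-separation
notion that does not transfer across chains, a backbone-backbone bond is
classed "short-range" when the CDR3 and peptide substructure positions
differ by at most 4, else "long-range"; this convention only matters for
how the large/small presets partition an (in practice tiny)
backbone-backbone contribution. All totals are in arbitrary surrogate
units and are **not** comparable to any physics-based score; the analyses
only ever use energy *differences* and their correlations.

dEnergy is E(child) minus E(parent) for a single-substitution step,
carried with the substitution and the substituted residue's minimum
heavy-atom distance to the peptide (minimum over peptide residues, for
residues contacting more than one). Correlation analyses use |dEnergy|:
substitution scores measure similarity without a direction, so the
magnitude of the perturbation is the comparable quantity. Signed values
are available behind a flag.

*Energetically valuable positions* of a template are the CDR3 positions
with minimal per-residue energy, per preset; when presets disagree, all
candidate positions are included (union). They are computed on the
unmodified template structure - the template is the one conformation all
of a cluster's models share, so its profile is the common reference; the
choice is recorded in output.

## Descriptor scales and substitution indices

47 descriptor scales per residue, 94 per contact pair (`cdr3.` and `p.`
prefixes): BLOSUM-derived indices Blos1-Blos10, Kidera factors KF1-KF10,
VHSE1-VHSE8, Cruciani PP1-PP3, z-scales Z1-Z5, FASGAI-style factors
F1-F6, and the five Atchley factors (a.pah, a.pss, a.ms, a.cc, a.ec).
Kidera, VHSE, Cruciani, z-scale and Atchley values are transcriptions of
the published tables. Two families are deterministic **reconstructions**,
clearly flagged in their documentation: Blos1-Blos10 are the ten leading
eigencomponents of the doubly centered BLOSUM62 similarity matrix (the
construction behind published BLOSUM-index scales), and F1-F6 are
unit-variance first principal components of anchor scale sets matching
the six generalized property axes (hydrophobicity, alpha/turn propensity,
bulkiness, composition, flexibility, electronic). Reconstructed scales
represent the same property axes but not the original numeric values;
every statistical conclusion the package's tests draw uses synthetic data
with effects planted *in the embedded tables*, so no test depends on
agreement with the original numbers.

Scales map to property groups (hydrophobicity, steric, electronic,
secondary structure) by published membership lists; a scale can serve
several groups, and `descriptor_primary_group()` resolves each scale to
one group by first listing, with unlisted scales "unassigned" since their
property content is mixed.

Substitution matrices come in three index kinds: half-bit scores (BLA),
bit-unit scores (SIJ) and target frequencies (QIJ), for BLOSUM62 and
BLOSUM100. Half-bit matrices are the authentic NCBI matrices shipped with
Biostrings. The sij/qij distribution files are not bundled; SIJ defaults
to BLA/2 and QIJ is reconstructed by inverting the log-odds relation
(q_ij proportional to p_i p_j 2^(s_ij in bits), with published BLOSUM
background frequencies, renormalized). Authentic NCBI files override the
reconstructions via `read_substitution_matrix()`. The *adjusted* index

> adjusted(a, b) = M[a, b] - (M[a, a] + M[b, b]) / 2

centers every identity substitution at zero, making scores comparable
across residues with different self-match scores.

## Statistical analyses

Three analyses consume the tidy dEnergy table or the pair-feature table:

1. Pearson correlation of each of the six adjusted indices against
   |dEnergy|, per preset and optimization arm, for all substitutions and
   for substitutions in contacting positions, pooled and per chain.
2. Pearson correlation of substitution remoteness (minimum distance to
   the peptide) against |dEnergy|, same stratification.
3. Spearman correlations between CDR3-side and peptide-side scales within
   each property group, with a Shapiro-Wilk normality test on each
   group's coefficient distribution and a report of the strongest
   positive and negative pairs. The default analysis slice is closest,
   side-chain contacts at mutated positions.

Cells with fewer than three observations or zero variance are reported as
not computable and skipped, never silently dropped. Multiplicity is
adjusted with Bonferroni by default (Benjamini-Hochberg selectable); the
adjustment method and the number of tests m are recorded on the result,
because an adjusted p-value is uninterpretable without its m. No attempt
is made to guess any other multiplicity universe.

## Energy classification with RFE and random forests

Per-residue contact energies are discretized into five equal-frequency
classes at the 20/40/60/80th percentiles. Following the order of
operations the procedure describes, bins are fitted on the pooled data
and the 70/30 train/test split (stratified by class) comes second; a
strict train-only mode is available, in which the split is a simple
random one (class stratification before binning would itself peek at
test-side values) and bin edges come from the training rows alone.
Recursive feature elimination over the 94 features uses random-forest
importance with cross-validation over candidate subset sizes
(caret's rfe); defaults are 10-fold CV, candidate sizes
{1..20, 25, 30, 40, 60, 94}, 500 trees, all configurable, seed mandatory.
The final forest is evaluated on the held-out split with accuracy (exact
binomial 95% CI), Cohen's kappa, the confusion matrix, and McNemar's test
against the majority-class baseline on the shared test rows (when both
optimization arms are run, the two arms' models can be compared on shared
rows instead; the comparator is recorded in the output).

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline needs, with ground truth
computed by brute force inside the generator (exhaustive permutation
enumeration for pathways, all-pairs distance scans for contacts) and
never by calling the modules under test.

* **Repertoires**: clusters grown distance-monotonically around random
  cores, so every planted member has at least one stepwise pathway, plus
  decoys that each violate exactly one membership rule (wrong V, wrong J,
  wrong length, wrong epitope, distance above 3, disconnected).
* **Toy complexes**: two idealized strands with residues spaced 12 A
  apart; planned contacts are realized by translating whole CDR3 residues
  toward their peptide partner until the pair's minimum heavy-atom
  distance hits the target, keeping unplanned pairs beyond 6 A. Residue
  types default to chemistry matching the intended interaction type
  (Asp/Arg for ionic, Ser/Ser for hydrogen bonds, Leu/Ala for van der
  Waals).
* **Descriptor-energy tables**: random residue pairs with a target
  planted as a linear combination of named scales plus a distance term
  and Gaussian noise; optionally the peptide residue mirrors the CDR3
  residue on a chosen scale to plant cross-side correlations.

None of this resembles real loop geometry: strands are straight, residues
are translated independently, and there is no MHC. Passing tests
therefore demonstrate that the *algorithms* are correct - rules applied
exactly, oracles matched, planted effects recovered with the right signs
and magnitudes - not that the surrogate energies reproduce measured
affinities or that real repertoires cluster this way.

## Numerical choices and test-scale conventions

* Hamming-1 graph connectivity via igraph components; members and
  pathways sorted lexicographically; closest-contact ties break toward
  the lower peptide position; valuable-position ties within 1e-9 are all
  included.
* Decomposition conservation is asserted at 1e-9 in surrogate units;
  preset nesting is exact by construction and asserted at 1e-12.
* Oracle-equivalence sweeps run 200 random repertoires (at most 20
  candidates each, a four-letter alphabet to make diamond motifs common)
  and 100 random toy complexes; these sizes give the brute-force oracles
  dense coverage of the rule combinatorics while staying small enough
  that the exhaustive enumerations remain exact.
* The chance-level check for the classifier shuffles labels over 20
  seeds on a 1000-row null (300-row test split): the null standard
  deviation of kappa at that size is about 0.03, so the +-0.1 band is a
  sound test of chance-level behavior rather than a coin flip on
  sampling noise. The planted-recovery fixture uses 500 rows with five
  informative hydrophobicity scales split across the CDR3 and peptide
  sides.

## Known limitations

* The surrogate backend cannot capture backbone relaxation, rotamer
  libraries or solvation physics; conclusions about real complexes
  require an external modeling backend or precomputed energy tables.
* Reconstructed Blos and F scales share axes with their anchor scales by
  construction, which inflates within-group collinearity relative to the
  original tables.
* Only CDR3-peptide interfaces are analyzed: no CDR1/CDR2, no CDR3-MHC
  contacts, no chain pairing.
* mmCIF input is not supported; CDR3 boundaries must be annotated, never
  inferred from structure.
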