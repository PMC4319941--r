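---
title: "corepan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corepan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical procedures `corepan` implements,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the methods literature leaves choices open. It states no empirical result
that the test suite does not itself compute.

## The analysis model

`corepan` treats a bacterial genome collection as a set of per-genome CDS
repertoires. Its unit of comparison is the **gene family** rather than the
gene, because across a genus the sequence divergence of homologous genes
is large enough that per-gene identity is uninformative.

### Gene families (50/50 rule)

Two genes are homologous when a local alignment of their protein sequences
has identity strictly above 50% **and** the aligned span covers strictly
more than 50% of the *longer* gene. Families are the connected components
of the resulting undirected graph (single linkage). Rationale: the source
rule is pairwise only; transitive closure is the minimal partition
consistent with it. A complete-linkage mode (`linkage = "complete"`,
hierarchical clustering on the 0/1 homology distance) is available for
sensitivity analysis. Note one consequence of single linkage that we
verify by test: chains of ~60%-identity pairs can join genes whose direct
identity is below 50%.

Each family's representative is its **longest member** (ties broken by
smallest gene id). Re-clustering after adding genomes is the defined
behaviour; families are not updated incrementally.

Two details are not stated in the methods literature we follow and are
package decisions: identity is computed over **all aligned columns
including gap columns** (the BLAST convention for `pident`), and the
coverage denominator is the longer gene's full length. Both are
configurable at the scoring/threshold level.

### Six-frame rescue

Gene prediction occasionally misses an ORF, which would turn a core family
into an accessory one. For every (family, genome) pair with no annotated
member, the family representative is aligned against all six reading-frame
translations of each assembly contig; the family is marked present when a
hit passes the same 50/50 rule measured against the representative length.
Rescue only flips absences to presences and never alters annotated
membership; hits are confined to single contigs (no crossing of contig
boundaries). We record presence only — rescued loci do not become
countable members.

### Pan/core accumulation and power fits

For a genome ordering, pan(n) and core(n) are the union and intersection
sizes over the first n genomes. Because the curve depends on the ordering,
means are taken over orderings: **all N! orderings when N ≤ 6**, otherwise
`permutations` (default 100) seeded random orderings. The "new families
per genome" statistic is read as the mean marginal pan growth,
(pan(N) − pan(1)) / (N − 1), averaged over orderings — an interpretation,
documented as such, of the published "+379 families per added genome"
phrasing.

Both curves are fitted with the power function y = κ·n^γ by ordinary least
squares on log y versus log n. The log–log form is closed-form and
deterministic; the RMSE is reported on the original scale. An open
pan-genome shows γ ∈ (0, 1) for the pan curve.

### ANI (fragment method) and AAI (filtered best hits)

ANI follows the fragment protocol of Goris et al.: consecutive
non-overlapping **1020-nt** windows per contig (a terminal remainder is
kept when ≥ 100 nt), each aligned to the other assembly; a window is
retained when its best hit reaches **≥ 30% identity over ≥ 70% of the
window length**, and the directional ANI is the mean identity of retained
windows. Since this paper-trail does not state directionality, the
package reports the **reciprocal mean** of both directions (symmetry
guaranteed; a one-way flag exists). These constants are exposed in
`run_config()` because the source article prints none of them — they come
from the cited method.

AAI filters blastp-style hits by three removal rules — (i) identity
< 30%, (ii) alignment length < 30 aa, (iii) alignment spanning < 70% of
"the entire length of the protein" — and keeps only the best surviving hit
per query (highest score; ties by identity, then smallest subject id).
Rule (iii)'s denominator is ambiguous in the source; we use the **query
protein length** and document the choice. Directional means are averaged
reciprocally. When no hit survives in either direction the distance is
undefined and a classed error (`corepan_undefined_distance`) is raised
rather than returning 0.

### Tree statistics

`nodes_to_mrca` counts the internal nodes on the tip→root path,
**excluding the tip and including the MRCA**, so the minimum value on any
tree with ≥ 2 tips is 1. The counting convention is a package decision
(the figure being emulated uses a strictly positive axis); it is invariant
to branch lengths by construction. Outgroup rooting re-roots on the edge
separating a monophyletic outgroup from the ingroup and errors otherwise.

The Wilcoxon rank-sum test uses midranks for ties. The exact distribution
is obtained by complete enumeration of the C(n_x+n_y, n_x) label
assignments when min(n_x, n_y) ≤ 10 and n_x + n_y ≤ 20; the exact
two-sided p is min(1, 2·min(tails)). Larger samples use the normal
approximation with tie-corrected variance and continuity correction. The
published comparison this emulates reports P = 0.003 without stating
sidedness or exactness; the package defaults to two-sided and records the
method in the result rather than guessing what was used.

### Alignment engine

A dependency-free Smith–Waterman with affine gaps (Gotoh) replaces BLAST.
Defaults: BLOSUM62 with gap open −11 / extend −1 for proteins; match +1 /
mismatch −1 with gap open −5 / extend −2 for nucleotides. The gap
convention charges `gap_open` for the **first** gap column and
`gap_extend` for each further column. Pairs whose DP matrix fits in
memory (default 8e6 cells) are solved exactly; longer subjects go through
k-mer seeding (k = 3 protein, k = 11 nucleotide): seed diagonals are
clustered, and the query is aligned exactly against a padded subject
window around each of the top three clusters. The full-DP path is the
correctness oracle for the seeded path in the test suite. Ambiguity codes
(N, X) never count as identical columns. No E-value statistics are
computed — retention decisions use identity/coverage thresholds only.

All-vs-all clustering uses a shared 3-mer prefilter (default threshold: 1
shared k-mer) plus a provably lossless length filter: identity > 50% over
> 50% of the longer gene forces the shorter gene to exceed a quarter of
the longer one's length. An `prefilter = FALSE` exact mode aligns every
length-compatible pair; tests assert both modes give identical partitions.

## The synthetic world

The generator states a desk-scale world loosely emulating a genus panel;
none of its parameters were taken from the emulated study (which describes
no generative model), and they are not tuned to test outcomes:

* **Tree**: Yule pure-birth topology (a uniformly chosen tip splits until
  N tips) with independent Exp(1) branch lengths — the simplest defensible
  clade model.
* **Repertoire**: `ancestral_family_count` (default 300) families at the
  root; along each branch of length ℓ, each present family is lost with
  probability 1 − exp(−loss·ℓ) and Poisson(gain·ℓ) new families arise in
  the subtree below. Defaults gain = 25, loss = 0.03 give an open
  pan-genome with a substantial conserved core at N = 10 genomes
  (default), echoing the accessory-heavy genus panels this emulates at
  1/10 scale.
* **Sequences**: each family has an ancestral gene of
  Poisson(`mean_gene_length_aa` = 110) codons drawn uniformly from the 61
  non-stop codons (typical bacterial gene length ~1 kb). Sites substitute
  independently along each branch with probability 1 − exp(−rate·ℓ);
  a substitution that would create an in-frame stop codon is redrawn
  (slightly deflating the realized rate in coding sequence — which is why
  ground truth is computed from realized sequences, not from the nominal
  rate). Intergenic spacers (50–200 nt, evolved like genes but without
  the stop constraint) separate genes in the assembly, so an assembly is
  never the plain concatenation of its CDS set and six-frame rescue is
  genuinely exercised.
* **Hosts**: the two clades below the root receive the two host labels
  ("bee", "human" by default), guaranteeing host-monophyletic groups;
  `host_assignment = "random"` provides the negative control.
* **Determinism**: one global seed drives named sub-streams (tree = seed,
  repertoire = seed+1, sequences = seed+2); identical configurations give
  byte-identical output files.

**Ground truth** is computed from realized data: per-pair expected
nucleotide identity is the Hamming identity over genes shared by the pair
(alignment-free because the simulator has no indels), and whole-genome
identity is recorded for pairs with identical family content (gapless
colinearity). This is what the ANI recovery tests compare against.

What the generator does **not** emulate — and hence what a green test does
not establish: indels, rearrangement, recombination and HGT (gene gain is
the only lateral event); codon-model realism (no transition/transversion
bias, no selection); genome-size and GC heterogeneity between lineages;
fragmented assemblies (one contig per genome); annotation errors other
than the ones injected deliberately in rescue tests. Recovery results on
this world say the *implementation* is faithful, not that the method is
robust to real-data artefacts.

## Numerical choices and degenerate inputs

* Strict inequalities at the 50/50 thresholds ("above 50%", "more than
  50%"); ANI/AAI retention thresholds are inclusive (≥ 30%, ≥ 70%) per the
  removal phrasing "less than ... were removed".
* Family ids are assigned by sorting each family's smallest member id;
  representatives break length ties by smallest id; best hits break score
  ties by identity then smallest subject id. Everything is deterministic
  under a fixed seed.
* `fit_power` refuses non-positive y; a constant series fits γ = 0
  exactly. Exhaustive curve enumeration engages automatically at N ≤ 6.
* Undefined distances (no retained fragments/hits) raise classed errors;
  they are never coerced to 0.
* Empty sequences, duplicate ids, unknown genomes/tips, ragged alignment
  blocks and non-separable outgroups are rejected with descriptive errors.

## Scope limits

Assembly, gene prediction, database annotation, multiple alignment and
maximum-likelihood tree inference are consumed as inputs, not
re-implemented; `concatenate_alignments()` covers only the supermatrix
step. Benchmark reproduction of published panel numbers (402 core
families, +379/genome, specific ANI/AAI values) requires downloading the
underlying assemblies and is outside the desk-scale test surface; the
acceptance suite instead checks the same machinery against synthetic
ground truth at 1/10 scale, with sweep sizes reduced to fit the test-time
budget.
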