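---
title: "Detecting DNA polymerase gene swapping in phage genomes: methods and design"
author: "polswap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DNA polymerase gene swapping in phage genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Replicative DNA polymerases (DNAPs) of tailed bacteriophages belong to three
essentially unrelated protein families (PolA, PolB, PolC). Although each
family is highly conserved, closely related phages sometimes carry DNAPs of
*different* families, with the flanking gene order untouched — evidence that
the polymerase gene was replaced "in situ" by an unrelated homolog, either
alone or en bloc with adjacent replication genes. `polswap` implements, at
desk scale, a complete analysis for detecting such swaps from genome
sequences alone, together with a synthetic phage-clade generator that plants
ground-truth swap events so that every stage of the analysis can be
validated end to end.

# The analysis pipeline

`run_pipeline()` executes the stages in order. All thresholds live in
`pipeline_config()` and are serialized (with an md5 hash) into every output
directory.

## ORF complements

`find_orfs()` scans all six reading frames for ATG-initiated,
stop-terminated ORFs of at least `min_orf_len = 75` nt (the stop codon is
included in the interval and in the length). An ORF strictly nested inside a
longer retained ORF on either strand is discarded; ties on length keep the
lower start coordinate. ORFs do not wrap around the genome end. ATG is the
only accepted start codon; GTG/TTG starts and alternative genetic codes are
out of scope.

## Reciprocal best hits and the genome distance

For each genome pair (A, B) the two ORF complements are compared with the
package's Smith–Waterman aligner (BLOSUM62, affine gaps open 11 / extend 1,
compiled in C++ and cross-checked against `Biostrings::pairwiseAlignment`
in the test suite). Bit scores use the gapped BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$; the E-value search space is
$n_\mathrm{subject} \cdot \bar L_\mathrm{subject} \cdot L_\mathrm{query}$,
a monotone surrogate for the BLASTP default. A pair (x, y) is a reciprocal
best hit (RBH) when each is the other's best-scoring partner (ties broken by
lexicographically smaller id) and both directional hits cover at least 50%
of the query with E ≤ 1e-4.

Because an all-vs-all scan of every genome pair is quadratic, the search is
seeded the way BLAST is: only protein pairs sharing at least `seed_min = 2`
distinct 4-mers are aligned. The seeded and exact searches are asserted
equal on simulator proteomes in the tests, and every oracle comparison runs
the exact mode.

With $C_{A,B}$ the length of genome A covered by the union of its RBH ORF
intervals, the genome distance is

$$D_{A,B} = 1 - \frac{C_{A,B} + C_{B,A}}{L_A + L_B},$$

clamped to $[0,1]$. The diagonal is fixed at 0: applied to a self-pair the
formula would measure the intergenic fraction, which is clearly not
intended.

## Genome tree, ultrametrization, and subtree decomposition

The tree is built by canonical Saitou–Nei neighbor joining (`nj_tree()`;
negative branch-length estimates clamped to zero, Q-ties broken by the
lowest index pair), midpoint-rooted, and made ultrametric by a single
proportional descent (`ultrametrize()`): with $m(v)$ the mean path length
from node $v$ to its descendant leaves, the root gets height $m(\mathrm{root})$
and each child $c$ of a node at height $H$ with branch $b$ gets height
$H\,m(c)/(b + m(c))$. This realizes "iteratively balancing subtrees,
descending from each internal node" in one pass and is exactly ultrametric
by construction; any other balancing scheme that preserves topology would
serve equally.

`cut_subtrees()` partitions the leaves into maximal subtrees of height at
most `subtree_depth = 0.15` — the genus-level unit of the analysis
(roughly one third of the total depth of the full-scale genome tree).
Node height (distance to descendant leaves) is only well defined on an
ultrametric tree, hence the precondition.

## DNAP annotation

`annotate_orfs()` aligns every predicted protein to a labelled reference
set; the best hit with E ≤ 1e-4 transfers its family (A/B/C, plus the
divergent divA1/divA2 categories) and in-family clade label. This replaces
the clustering/profile chain of the full-scale analysis (MMSEQS2 +
HHSEARCH/HHALIGN), which is tool glue around reference curation: the swap
detection itself needs only family and clade labels, and externally
computed hit tables can be imported as TSV.

`check_catalytic()` reads the catalytic motif residues (Pol motifs A/B/C of
the palm domain; 3'-exonuclease motifs I–III) through the pairwise
alignment to the best reference; `retain_active_calls()` keeps calls whose
polymerase motifs are intact and whose alignment covers at least 80% of the
reference. The pipeline applies this screen whenever a motif table is
supplied — without it, marginal short-coverage hits occasionally produce
spurious second DNAP calls — and falls back to the coverage filter alone
otherwise. Exact residue identity is required by default; residue classes
(e.g. D/E) are configurable per position.

## Heterogeneity, swap clades, and event counting

Within each depth-0.15 subtree two patterns are flagged
(`detect_heterogeneous_subtrees()`): type (i), different single-copy DNAP
families in different genomes (the swap signature), and type (ii), one
genome carrying two DNAPs of different families. Heterogeneous subtrees are
extended upwards (`group_swap_clades()`) while the parent stays below
`clade_max_depth = 0.45` and the sister lineages still contain DNAP-encoding
genomes; overlapping or nested ascents merge into maximal clades.

Replacement events are counted by Sankoff small parsimony
(`infer_swap_events()`) over composite `family/clade` states with unit
change cost (inter- and intra-family costs configurable). The minimum
change count is provably the parsimony optimum (the test suite compares
against exhaustive enumeration); backtracking ties prefer the parent state,
then lexicographic order, so runs are deterministic. Events are classified
intra-family when only the clade part changes. Genomes without a DNAP are
excluded from the leaf set by default, matching how swaps are counted among
DNAP-bearing genomes; the direction of events is deliberately not asserted
— they are unordered state changes on edges unless a root state is
supplied.

## Topology validation (AU test)

`compare_constrained()` contrasts the unconstrained marker-gene (TerL) NJ
topology with the topology constrained to keep each DNAP family's genomes
together. Branch lengths of *both* topologies are re-estimated by
non-negative least squares from the same F81-corrected distance matrix, so
identical topologies receive identical likelihoods. Per-site
log-likelihoods come from Felsenstein pruning under an F81-type protein
model, $P_{ij}(t) = e^{-\beta t}\delta_{ij} + (1 - e^{-\beta t})\pi_j$ with
$\beta = 1/(1-\sum_k \pi_k^2)$ — chosen for its closed-form transition
probabilities; gaps are missing data; site log-likelihoods are floored at
−745. This is deliberately simpler than the VT/Q.pfam + rate-heterogeneity
models of the full-scale analysis: it suffices for the qualitative
constrained-vs-unconstrained contrast on synthetic data, and externally
computed site-likelihood matrices (e.g. from IQ-TREE) can be supplied as
TSV.

`au_test()` implements the Approximately Unbiased test by multiscale RELL:
at each scale $r \in \{0.5, 0.6, \ldots, 1.4\}$, $B = 10{,}000$ replicates
of $\lceil rn \rceil$ sites are resampled with replacement (ties split
equally among the best topologies), bootstrap proportions are clipped to
$[1/(B{+}1), 1-1/(B{+}1)]$ and fitted by weighted least squares to
$\Phi^{-1}(1-\mathrm{bp}(r)) = d\sqrt{r} + c/\sqrt{r}$ with binomial
delta-method weights; $p_{AU} = 1 - \Phi(d - c)$. Runs are bit-reproducible
given the seed; degenerate proportions (0 or 1 at every scale)
short-circuit to the clipped extremes.

## Average nucleotide identity

`ani()` implements an OrthoANI-style fragment method: 1000-nt consecutive
fragments, each placed on the partner genome by 12-mer seeding (both
strands) and aligned locally (match +1, mismatch −1, gap open 5, extend 2)
against a window of ±200 nt around the seeded diagonal rather than the
whole genome — full-genome local alignment of every fragment is quadratic
and infeasible at 100 kb scale. Fragments reaching 70% identity over 70% of
their length are paired by reciprocal best fragment; the reported ANI
averages the two directions. Trailing partial fragments are discarded; a
pair with no retained fragments is reported "below detection" rather than
0. Because local alignment trims poorly matching ends, ANI on an
i.i.d.-mutated copy runs a few tenths of a percent above the naive
expectation — consistent with how fragment-based ANI tools behave, and well
inside the ±1 percentage-point tolerance used for published values.

# The synthetic clade generator

`simulate_clade()` emulates exactly the situation the analysis is built
for: a clade of related phage genomes with conserved gene order, one DNAP
inside a replication block, and rare replacement events.

* **Tree:** Yule (pure birth) on `n_genomes = 20` leaves, rescaled to
  root-to-leaf height `tree_height = 0.25` expected amino-acid
  substitutions per site — divergences where homology detection is easy but
  sequences are far from identical.
* **Genes:** `n_genes = 30` ancestral proteins of 120–300 aa (DNAP 400 aa)
  drawn i.i.d. from an average protein composition, evolved
  site-independently under the same F81-type model the likelihood machinery
  uses. Position 1 (initiator methionine) and six designated catalytic
  motif positions of the DNAP are invariant — catalytic residues are
  strongly conserved in reality, and without this the activity screen would
  flag ordinarily evolved copies as degraded.
* **Donors:** one independent random 400-aa donor per family/clade state
  (A1, A2, B1, B2, C1), all sharing the same motif positions and residues.
  Donors are mutually unrelated *including within a family*: the
  RBH-coverage distance registers a replacement only when the new gene has
  no reciprocal hit in unswapped relatives, and the in-family polymerase
  groups distinguished at the clade level are themselves deeply divergent.
  Each donor carries unrelated block-partner proteins for en-bloc events.
* **Events:** 1–3 events on non-nested edges with pairwise-distinct target
  states (this guarantees the planted count equals the parsimony minimum)
  and at least one inter-family target — swap clades are ascertained by
  cross-family heterogeneity, so a purely within-family event set would be
  invisible to the family-level screen, as it is in the real analysis.
  Modes: `dnap-only` or `en-bloc` (DNAP plus `en_bloc_k = 2` downstream
  block genes). The donor sequence enters at the child node of the event
  edge and evolves normally below it.
* **Genomes:** uniform synonymous back-translation with a terminal TAA,
  joined by intergenic spacers of 2–50 random nt flanked by 22-nt cassettes
  carrying stop codons in all six frames. The cassettes guarantee that no
  spurious ORF can span or engulf a planted gene, so `find_orfs()` recovers
  every planted protein exactly; the spacer lengths give the ~90% coding
  density typical of tailed phage genomes. Codon usage modelling and
  nucleotide-level indels are out of scope.

Everything is deterministic given one seed.

## What the simulations do and do not show

The generator conserves the full gene repertoire, so between unswapped
relatives every gene keeps a full-coverage RBH and the genome distance
saturates at its intergenic floor: the *within-state* branching order of
the genome tree is therefore not recoverable at these divergences, and no
test asserts it. What the swap analysis actually requires — that each
swapped group is set off by the coverage loss of its replaced block, lands
in a heterogeneous subtree, and contributes exactly its planted events to
the parsimony count — is present and is what the end-to-end suite asserts
(perfect leaf family/clade recovery; exact event counts in at least 18 of
20 replicates).

The AU validation suite additionally ascertains *strong-signal* clades
before testing: a simulated clade qualifies only when the family-separating
constraint measurably conflicts with the true tree, operationalized as the
constrained topology's least-squares fit distorting at least one true
pairwise distance by ≥ 0.1 substitutions per site. This mirrors how the
real swap clades are recognized — families interleaved across the genome
tree, not forming adjacent blocks. When the planted foreign-family groups
happen to attach next to each other, the constraint is (nearly) satisfiable
and the AU test correctly declines to reject; such clades are outside the
condition the rejection claim is about.

In real data the distance additionally carries gene-content
turnover and alignment-detectability decay, which the desk-scale simulator
deliberately omits; passing tests validate the machinery of the pipeline,
not the phylogenetic resolution of the coverage distance on turnover-free
data.

# Numerical choices and degenerate inputs

* Distances are clamped to $[0,1]$; NJ clamps negative branch estimates to
  0; all tie-breaks (Q criterion, best hits, Sankoff backtracking) are
  lexicographic and deterministic.
* `ultrametrize()` guards zero-length paths ($b + m(c) = 0$ gives height
  0); `cut_subtrees()` refuses non-ultrametric input (relative tolerance
  1e-6) instead of silently mis-assigning heights.
* 2-taxon trees are a midpoint-split edge; 3-taxon topology comparisons
  collapse to the single unrooted topology and report $p_{AU} \approx 0.5$
  for both entries.
* Codons containing N translate to X; X and gaps are missing data in the
  likelihood; an observed residue with zero frequency floors the site
  log-likelihood at −745.

# Problem sizes

The shipped validation suites run at the sizes the analyses above were
designed around: 20 end-to-end replicate clades of 20 genomes × 30 genes;
20 AU replicates of 12 genomes with a ~500-aa marker at $B = 10{,}000$;
100 random 8-leaf additive matrices for NJ exactness; 200 random parsimony
instances against exhaustive enumeration; 20 random 10-kb sequences against
the brute-force ORF oracle. `scripts/acceptance.R` recomputes the headline
quantities on one clade of each kind from a single seed.

# Known limitations

* The genome distance measures shared detectable gene content, not
  substitution divergence; below the detectability limit it is flat (see
  above).
* The AU machinery uses a single-rate F81-type model and distance-based
  branch lengths; absolute p-values under richer models will differ, and
  only the qualitative rejection behaviour is claimed.
* Best-hit annotation cannot discover genuinely novel divergent DNAP
  groups; it only transfers labels from the provided references.
* ANI below ~70% fragment identity is reported as "below detection" rather
  than extrapolated.
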