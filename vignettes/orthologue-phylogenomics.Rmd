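---
title: "Methods: orthologue phylogenomics and floral gene classification"
author: "orthophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthologue phylogenomics and floral gene classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthophylo)
```

## The problem

Woody bamboos flower rarely and synchronously, so genomic resources are
sparse and phylogenetic questions in the subfamily (Bambusoideae) have long
been argued from plastid markers. Two competing tribe-level topologies are
in play: a *nuclear hypothesis* in which the woody tribes (tropical
Bambuseae + temperate Arundinarieae) are monophyletic with the herbaceous
Olyreae as their sister, and a *plastid hypothesis* in which Olyreae is
sister to Bambuseae, making the woody bamboos paraphyletic. Deciding
between them from transcriptome data requires (i) large sets of single-copy
nuclear orthologues extracted reproducibly from per-species transcript
sets, (ii) per-gene trees whose support for each hypothesis can be counted,
and (iii) careful handling of gene families where paralogy is the norm —
the MADS-box floral regulators (ABCDE classes plus the *SOC1*- and
*SVP*-like flowering-time genes) being the case of interest.

`orthophylo` implements that pipeline end to end at desk scale, together
with a seeded synthetic-data generator so that every stage is testable
against known truth without raw sequencing data.

## Similarity search

The search engine is an affine-gap Smith–Waterman aligner (compiled code;
a global Needleman–Wunsch mode shares the kernel). A gap of length $L$
costs $g_{open} + L\,g_{ext}$. `seeded_search()` computes the full optimal
local alignment for every query/subject pair that shares at least one
exact $k$-mer (both strands in nucleotide mode), so any alignment
containing an exact seed word and exceeding the score cutoff is found;
multiple high-scoring segments per pair are collapsed to the single best
alignment by raw score, because the downstream orthology rule counts
*subjects*, not segments. There are no X-drop or banding heuristics.

Scores are reported on the Karlin–Altschul scale,
$S' = (\lambda S - \ln K)/\ln 2$ and $E = m\,n\,2^{-S'}$, with search
space $m \times n$ taken as query length times the summed database length
and no edge-effect correction. $\lambda$ and $K$ are fixed scheme
constants (nucleotide $+1/-2$, gaps $5/2$: $\lambda = 1.28$, $K = 0.46$;
protein BLOSUM62, gaps $11/1$: $\lambda = 0.267$, $K = 0.041$): the
pipeline's decisions depend only on threshold crossings, which the
constants merely rescale, so estimating them from data would buy nothing
here. Whether the $10^{-5}$ threshold is applied per pair or database-wide
is a genuine ambiguity; we expose the database length through the search
interface and default to database-wide $n$.

Hits pass a three-way filter — E-value $\le 10^{-5}$, alignment length
$\ge 100$ (bp; protein searches use a 50-aa floor), identity $\ge 0.70$ —
with inclusive comparisons at the stated values ("maximum"/"minimum"
wording implies inclusivity). Identity counts identical-residue columns
over *all* alignment columns; gapped columns inflate the denominator only.
This matches the tabular-output convention; no authoritative definition
exists, so the choice is recorded here as the package's contract.

## Orthologue clusters

Anchored on two reference gene sets (a rice-like anchor set and a second
grass reference), clusters are built by three rules, applied after
filtering:

1. **Reciprocal uniqueness.** An anchor pair $(a, b)$ is kept iff $b$ is
   the only subject $a$ hits and vice versa. "Exactly one hit" counts
   distinct subjects after filtering — the only reading that makes the
   rule well-defined once segments are collapsed. Filtering before the
   uniqueness test follows the stated order of operations.
2. **Best membership.** For each anchor and each transcript set, the
   single hit with the highest bit score joins the cluster; ties break by
   higher identity, then lexicographic subject id (the tie-break is
   arbitrary but must be deterministic and documented). The member
   contributes the homologous region its hit covers, reverse-complemented
   when on the minus strand so clusters are co-oriented.
3. **Completeness.** Only clusters with a member from every required taxon
   survive. The second reference joins clusters exactly like a transcript
   set (best bit-score hit per anchor) and is required by default.

## Alignment, supermatrix, trees

Per-cluster alignment is deterministic progressive alignment: pairwise
$k$-mer distances feed an average-linkage guide tree, profiles are merged
by affine-gap global DP, and all ties resolve by input order. A
consistency-based aligner would be marginally more accurate on hard cases,
but alignment quality is not the decision surface here — determinism and
testability are, and an external FASTA-in/FASTA-out aligner can always be
substituted upstream of `alignment()`. Clusters concatenate into a
supermatrix with a partition table (0-based half-open column ranges);
`strip_gap_columns()` removes every column containing at least one `-`
(ambiguity codes are ordinary states) and remaps partition boundaries to
surviving columns. Stripping is idempotent and column provenance stays
bijective.

Tree estimation is classical neighbor joining on Kimura two-parameter
distances with pairwise deletion: for each pair, transitions $P$ and
transversions $Q$ are counted over the columns where both rows carry an
ungapped A/C/G/T and $d = -\tfrac12 \ln\big((1-2P-Q)\sqrt{1-2Q}\big)$.
Saturated pairs (log argument $\le 0$) are capped at $d = 10$ — far above
any simulated distance — with a warning. Negative NJ branch estimates are
clamped to zero and Q-criterion ties break on the lexicographically
smallest pair of subtree representative labels, so results do not depend
on input order. A likelihood engine (GTR+Γ+I) is deliberately out of
scope: the quantities this package reports — topology counts, consensus,
support — are estimator-agnostic, and NJ on additive matrices is exact,
which gives the test suite a sharp oracle (recovery of 100 random additive
matrices to $10^{-9}$).

Bootstrap support resamples alignment columns with replacement, re-runs
NJ, and scores each internal bipartition of the point tree by its
pseudoreplicate frequency. Majority-rule consensus keeps exactly the
bipartitions above the threshold (default 0.5, where compatibility is
guaranteed), annotated with their frequencies; the consensus is
descriptive output — headline numbers come from per-tree classification.

## Hypothesis counting and the percentage convention

Each gene tree is rooted at the designated outgroup (the edge subtending
that leaf) and tested for exact monophyly of each hypothesis clade
(a polytomy counts only via an exact descendant-set match; no soft
credit). Hypotheses are evaluated independently, so one tree may support
several. Trees where the outgroup attaches inside a hypothesized clade
simply fail the monophyly test; no special class exists for them.

Reported percentages are **truncated** to two decimals,
$\lfloor c/t \cdot 10^4 \rfloor / 10^2$, never rounded. Recomputing the
published count/percentage pairs identifies truncation unambiguously
(2374/3878 = 61.2171… prints 61.21; rounding would print 61.22), so the
package adopts it as the report's contract and the test suite pins all
five published pairs.

## MADS-box identification and classification

Candidates are transcripts (or their longest-ORF translations, helper
provided) with at least one filtered protein-mode hit from the labeled
reference anchors **and** length strictly over 100 aa. Conspecific
redundancy — the same gene recovered twice by different assembly routes —
is removed by single-linkage grouping at pairwise identity above 0.95,
measured on the optimal local alignment (overlap only). Identity alone is
not a sufficient linkage criterion: unrelated proteins routinely share
short perfect local matches, so linkage additionally requires the
alignment to span at least 50 columns (the protein filter floor). Each
group collapses to one copy, longest-first, by consensus over the union of
aligned positions — earlier (longer) sources win disagreements and shorter
sources fill uncovered regions — so "reduce to one copy" and "merge
partial assemblies" are the same operation.

Family assignment builds one NJ tree over all copies plus anchors
(distances $1 -$ global-alignment identity; a p-distance with no rate
correction, since only relative placement matters) and gives each copy the
family of the *smallest clade containing it together with anchors of
exactly one family*; clades mixing families leave the copy unassigned.
This is the deterministic version of assignment-by-inspection. Per-family
trees are then re-estimated from a progressive protein alignment of the
family's members, rooted at the family's first reference anchor, with
column-bootstrap support when requested. Copy counts tabulate per family
and taxon with margins; unassigned copies are excluded from the table and
reported separately. Sister-group summaries (the fraction of a taxon's
copies whose sister leaves are all other-species bamboo copies) use the
same truncated-percentage convention.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with defaults fixed once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| taxa | 6 labels | two reference outgroups, one herbaceous, two tropical + one temperate woody |
| `n_genes` | 500 | genes per simulation |
| `concordance` | 0.62 | probability a gene tree matches the species topology |
| alternative topology | plastid rearrangement | the single discordant draw, so counts map onto the two hypotheses |
| `kappa`, `base_freqs` | 2, (.3, .2, .2, .3) | HKY substitution; the simplest model with both a ts/tv ratio and unequal frequencies |
| `branch_scale` | 0.03 subs/site/unit | keeps anchor-to-ingroup identity ≈ 84 % (above the 70 % filter) while internal edges still carry ≈ 10+ expected substitutions at the default lengths |
| `gene_length_range` | 300–900 bp | uniform; no claim of realism, only a configurable range |
| branch jitter | lognormal, mean 1, σ = 0.3 | positive multiplicative length noise |
| `paralogue_rate` | 0.05 | Poisson-mean extra copies per gene per taxon; 0.35 extra subs/site, truncated to a uniform 50–100 % window (the package's source of gapped alignment columns) |
| `variant_rate` | 0.05 | probability of a conspecific near-duplicate at 2 % divergence (> 95 % identity), exercising the merging rules |

Sequences evolve by applying the exact HKY transition kernel
$P(t) = e^{Qt}$ (eigendecomposition, rate-normalised) independently per
site along each branch; the root is drawn from the stationary
frequencies. Indels are **not** simulated — gaps arise only from truncated
paralogues and the alignment stage. The MADS generator simulates one
unrelated ancestral protein per class (150–300 aa), anchors at 8 % and
copies at 10 % divergence — placing within-class identity near 0.8,
comfortably above the 0.70 search floor and below the 0.95 merge bar —
plus random decoy proteins that fall below every filter by construction.
Identical configurations (including the seed) produce byte-identical
FASTA/newick/TSV outputs.

What the generator does *not* emulate: read-level error and coverage,
assembly artifacts (beyond idealised variants/truncations), indels, rate
heterogeneity across sites, expression levels, allopolyploidy. Passing
tests therefore demonstrate the correctness of the pipeline's logic under
its stated model, not robustness to every pathology of real
transcriptomes.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full chain at 500
genes × 6 taxa (the simulation's native condition), the MADS chain at the
72-copy reference parameterisation with 20 decoys, oracle comparisons on
1,000 random short pairs, NJ recovery on 100 random additive matrices, and
bipartition/monophyly enumeration over all unrooted topologies with 4–7
leaves. The pipeline's search uses seed word size 13 (the scheme default
is 11): at the simulated identities seeding sensitivity is unaffected
while chance seed matches drop by an order of magnitude. Other fixed
numerics: saturation cap $d = 10$; DP and guide-tree ties by input order;
NJ ties lexicographic; gap character `-` only.

## Known limitations

- NJ point estimates carry no model of rate heterogeneity; on real data
  with strong among-site variation the per-gene counts would differ from a
  likelihood analysis (the counting machinery itself is estimator-
  agnostic and accepts any newick input).
- The E-value calibration is nominal (fixed $\lambda, K$); absolute
  E-values should not be compared across schemes.
- Family assignment presumes anchors bracket every family; copies from
  families without anchors are reported unassigned rather than discovered.
- The progressive aligner is not consistency-based; deep or indel-rich
  homologies would benefit from substituting an external aligner upstream.
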