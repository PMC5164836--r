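---
title: "Methods: coalescent species trees and pathway loss mapping in redphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent species trees and pathway loss mapping in redphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redphylo)
```

# The problem

Red algae (Rhodophyta) span unicellular extremophiles to large seaweeds, and
the branching order of their major classes — in particular the position of
the seaweeds (Bangiophyceae + Florideophyceae) relative to the other
mesophilic lineages — has been hard to settle from small gene sets.
`redphylo` implements a complete phylogenomic workflow for this setting:
select single-copy nuclear orthologs from clustering output, build species
trees from hundreds of per-gene trees under the multispecies coalescent,
quantify uncertainty with a two-level bootstrap, and then use the resulting
species tree to reconstruct the history of metabolic pathway genes — here
the cytosolic mevalonate (MVA) and plastid methylerythritol-phosphate (MEP)
routes to isopentenyl pyrophosphate — by Dollo parsimony.

The package is organised in the classic R modelling idiom: `mpest()` is a
fitting function returning a classed object with `print`, `summary`, `coef`,
`logLik` and `simulate` methods; `mpest_bootstrap()` and `dollo_losses()`
return classed results with their own methods.  Everything upstream
(filters, concatenation, resampling) is plain functions over plain data.

# Ortholog selection

Input is an OrthoMCL-style `groups.txt` (clusters of `taxon|gene` members),
a taxon table partitioning taxa into the red ingroup and green outgroup, and
per-gene trimmed protein alignments.  A group is single-copy usable iff

* no taxon contributes two or more members,
* at most `max_missing_red = 3` red taxa are absent,
* at most `max_missing_green = 1` green taxon is absent,

and its alignment is retained iff it has strictly more than 150 columns and
at least 15 sequences.  Rejection reasons are evaluated in a fixed order
(multi-copy, then red missingness, then green missingness) so reports are
reproducible.  The sequence-count filter is applied to the full alignment,
before outgroup reduction: the threshold describes the evidence available
for the gene, not the post-processing.  `reduce_outgroup()` then keeps a
single green sequence per gene, by the fixed priority Chlamydomonas
reinhardtii, Chlorella variabilis, Micromonas pusilla.

`trim_gap_columns()` is labelled plumbing: a gap-fraction trimmer (drop
columns with more than 50% gaps) standing in for score-based trimming tools
that normally run upstream.  It is not equivalent to them and carries no
scientific claim.

# The pseudo-likelihood species tree

The estimator works from rooted triples.  For a species triple whose two
speciation nodes are separated by an internal path of `T` coalescent units
(1 unit = 2N generations), the probability that a gene tree matches the
species-tree resolution is

$$p_c(T) = 1 - \tfrac{2}{3} e^{-T},$$

and each discordant resolution has probability $\tfrac13 e^{-T}$.
`count_triples()` reduces a set of rooted gene trees to the per-triple
resolution counts — the sufficient statistic — and `pseudo_loglik()` scores
a candidate species tree by treating triples as independent multinomials
(constant multinomial coefficients are omitted; the value is comparable
across topologies on fixed counts).  This is the maximum pseudo-likelihood
(MP-EST-style) formulation; triples are not really independent, so the
objective is a composite likelihood: good for point estimation, not for
likelihood-ratio testing.

Numerical choices:

* Internal branch lengths are optimized by L-BFGS-B with analytic gradients
  inside `[1e-8, 20]` coalescent units.  The objective is concave in the
  per-triple path lengths, so box-constrained quasi-Newton is reliable; the
  upper bound matters only numerically ($p_c(20) - 1 < 10^{-8}$).
* Terminal branch lengths carry no triple information and are reported as
  `NA`.
* Topology search is hill climbing over rooted NNI neighbourhoods (two
  neighbours per internal non-root node), accepting a move only if the
  optimized objective improves by more than `tol = 1e-8`, with previously
  visited topologies cached by a canonical Newick form.  Ties between
  equally scoring trees break to the lexicographically smallest canonical
  string, making the search deterministic given its seed.
* The default start tree is a greedy agglomeration: repeatedly merge the
  pair of clusters with the highest mean pairwise triple support.  Restarts
  (default `n_restarts = 10`; the validation runs use 2, which was already
  sufficient at the design scale) perturb the start by 3 random NNI moves.
* Triples with zero total count contribute nothing and are skipped.
* Gene-tree polytomies leave a triple unresolved; unresolved triples are
  not counted toward any resolution.

# Two-level bootstrap

`mpest_bootstrap()` implements nonparametric uncertainty propagation at
both the gene and the site level: each replicate resamples genes with
replacement, then resamples alignment columns (jointly across rows, so
within-column linkage is preserved) within each sampled gene, estimates a
rooted tree per gene, fits the pseudo-likelihood species tree, and finally
summarises replicates by majority-rule consensus with percent supports.

Per-gene trees default to `estimate_gene_tree()`: neighbor joining on the
Poisson-corrected protein distance $d = -\ln(1 - p)$, with the mismatch
proportion $p$ computed over pairwise-complete (both rows non-gap) columns.
Saturated or non-overlapping pairs are capped at distance 10 with a
warning.  This internal estimator keeps the pipeline dependency-free and
fast; any external maximum-likelihood program can be plugged in by passing
a `gene_tree_fun` that wraps it, the pluggable surface being a plain R
function `(alignment, outgroup) -> phylo`.

The outgroup exists only to root the gene trees.  After rooting, outgroup
tips are pruned before triple counting: outgroup reduction may retain a
different green species in different genes, so the outgroup cannot act as a
single species label in the coalescent model.  Consensus supports are
therefore supports on the red-algal tree.

Seeding: the master seed draws one sub-seed per replicate, and each
replicate seed draws one sub-seed per gene, so replicates (and individual
gene resamples) are independently reproducible.  Rerunning with the same
master seed reproduces the consensus byte for byte.

A failed replicate (e.g. a crashing external backend) is logged and
skipped; the run errors when more than 10% of replicates fail.

# Consensus

`consensus_tree()` tallies non-trivial clades across rooted trees.
`"strict"` mode keeps clades occurring in strictly more than half of the
trees (ties at exactly 50% are excluded); `"extended"` mode — the default,
matching the common `consense` default behaviour — then greedily adds the
remaining clades in descending frequency when compatible with everything
accepted so far, with ties broken lexicographically for determinism.  Node
labels carry the percentage of input trees containing the clade, rounded to
one decimal.  Both variants are provided because published analyses rarely
state which was run.

# Dollo loss mapping

For a presence/absence/ambiguous character over the species-tree leaves,
`dollo_losses()` places a single gain at the MRCA of present leaves
(optionally forced to the root for characters presumed ancestral) and finds
the minimal set of loss edges: the maximal subtrees inside the gain clade
whose leaves are all non-present and that contain at least one strict
absence.  One loss per such subtree is both sufficient and necessary, and
the placement is the highest valid one; the minimality is verified against
exhaustive search over loss-edge subsets in the test suite.

Ambiguity encodes the evidence structure of mixed data: absence from a
transcriptome is weak, so `call_presence()` scores it `?` by default
(configurable to `absent` when absences have been independently confirmed,
e.g. by searches against both genome and transcriptome data).  Partial
genomes are treated as genome-grade evidence.  Ambiguous leaves never force
a loss but may be absorbed into an adjacent loss clade.  A consequence
worth knowing: the inferred loss count is invariant to how clades whose
leaves share one state are resolved.

The per-enzyme calls are the primary result.  The pathway-level call in
`pathway_call()` — present iff at least half of the designated core enzymes
(for the MVA pathway: HMGR, MVK, PMK, MVD, the 3rd–6th enzymes) are present
— is this package's own aggregation construction, provided because some
downstream questions need a single per-taxon bit; the threshold is
configurable and no stronger claim is attached to it.

# What the simulators emulate (and what they do not)

`sim_msc_gene_trees()` draws genealogies one lineage per species under the
exact multispecies coalescent: within a species-tree branch, `k` lineages
coalesce at rate `k(k-1)/2` with truncation at the branch length, and the
root branch is unbounded.  `sim_alignment()` evolves sites under a 20-state
equal-exchangeability model (change probability
$(19/20)(1 - e^{-(20/19)b})$ along a branch of length `b`
substitutions/site), for which composing branches is exact.  Coalescent
branch lengths map to substitutions/site through a single rate (default
0.05 substitutions/site per coalescent unit — only relative divergence
matters for the tests, and this value keeps simulated identities in the
comfortably alignable range).  Missingness is emulated at the orthogroup
level by dropping a taxon from a gene.

Deliberately not emulated: realistic amino-acid exchangeabilities (LG/WAG),
among-site rate variation, indels, alignment error, hidden paralogy, and
lateral transfer.  Passing the simulation-based tests therefore shows the
estimators are correct under their own model assumptions — coalescent
discordance plus i.i.d. substitution noise — not that they are robust to
the full error structure of real transcriptome data.

The bundled design mirrors the 15 red + 3 green taxon sampling:
`rhodophyta_taxa()` records class and data-type annotations, and
`rhodophyta_tree()` the reference topology with configurable
coalescent-unit branch lengths (default 1.0 throughout, a regime with
appreciable but resolvable incomplete lineage sorting: concordance
$p_c(1) \approx 0.755$).  Within-Porphyridiophyceae branching order is not
constrained by the analyses this package reproduces; the bundled topology
resolves it as (Porphyridium,(Erythrolobus,Timspurckia)), which no
downstream quantity depends on.

# Validation scales

The test suite validates each stage at sizes chosen to make sampling error
negligible relative to the asserted tolerances while keeping the suite
quick: closed-form concordance at $10^5$ genealogies (tolerance 0.005),
branch-length recovery at $10^4$ triples (tolerance 0.05), species-tree
recovery with 298 gene trees across 20 seeds, and the two-level bootstrap
at 15 taxa x 50 genes x 200 columns with 20 replicates.
`scripts/acceptance.R` re-runs the same computations end to end and writes
the headline numbers as JSON.

# Known limitations

* The pseudo-likelihood is a composite likelihood: its value is not a
  probability of the data, and model comparison across datasets is not
  meaningful.
* One lineage per species: within-species polymorphism and multi-allele
  sampling are out of scope.
* The NJ gene-tree backend underperforms maximum likelihood on saturated or
  rate-heterogeneous genes; plug in an ML backend where that matters.
* Dollo parsimony excludes regain by construction; characters that can be
  re-acquired (e.g. by lateral transfer) violate the model.
* PhyloBayes/CAT concatenation inference and per-gene model selection are
  intentionally outside the package: the supermatrix writer exists to hand
  data to such tools.
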