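---
title: "Methods: uniparental lineage analysis in founder isolates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uniparental lineage analysis in founder isolates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, the design choices made where
the problem admitted several defensible answers, and the limits of what the
synthetic-data validation can show.

## Haplogroup model

mtDNA and the non-recombining Y are inherited clonally, so their diversity
is organised as a phylogeny of haplogroups, each clade defined by the
variants gained (and occasionally reverted) on its root-to-node path. The
package represents a reference phylogeny as a rooted tree whose nodes carry
*defining variant tokens*:

* substitutions with or without the ancestral base (`A1692G`, `1692G`);
* bare positions (`1692`) — the shorthand common in the haplogroup
  literature; their derived allele is a wildcard that matches any base
  observed at the position;
* deletions (`8281-8289d`) matched by their exact range;
* insertions (`573.1C`) and named markers (Y SNP labels such as `P293`),
  matched by string identity;
* a trailing `!` marks a back mutation: accumulating along a path it
  *removes* the earlier variant at its position, following the Phylotree
  convention.

The *cumulative variant set* `E(v)` of node `v` is the union of defining
variants from the root down to `v`, with back mutations resolved. Trees are
read from a deliberately simple three-column TSV (`node, parent, variants`)
because no canonical machine-readable format exists for these phylogenies;
`write_reference_tree()` inverts the reader exactly.

## Classification score

A sample is a *variant profile* `O`, the set of differences from the
reference sequence (from consensus sequencing or a SNP panel). For each
node, with `M` the one-to-one matching between `E` and `O` (wildcards
compatible with any allele at the position), the score is the symmetric
Kulczynski-style mean

$$s(v) = \frac{1}{2}\left(\frac{|M|}{|E|} + \frac{|M|}{|O|}\right),$$

with an empty-denominator term defined as 1 (the empty profile matches the
root perfectly, and the root matches everything at 0.5 once a profile is
non-empty). The two terms are the haplotype's recall and precision, so the
score penalises both missed expected variants and private extras. The
maximiser is the call; ties break toward greater path depth (the most
specific clade), then lexicographically, making output deterministic. The
classification literature for these markers describes "closest match"
without fixing a formula, so the concrete score is this package's choice;
it is validated by self-consistency (every node's own cumulative set is
called back, uniquely, at score 1) and by equivalence with an independent
exhaustive scorer on random instances, rather than by matching any
particular published caller sample-by-sample.

An optional positional mask (e.g. the hypervariable 16182/16183/16519
positions) removes sites from both `E` and `O` before scoring; the default
mask is empty. `collapse_haplogroup_frequencies()` bins calls at or below a
focal ancestor as `"<ancestor>[x]"` and everything else by its top-level
clade, which is how cohort summaries such as "fraction of genomes in clade
B4a1" are produced.

## In-silico 9-bp deletion screen

Haplogroup-B mtDNA carries the Polynesian-motif deletion: loss of one copy
of the CCCCCTCTA tandem repeat between COII and tRNA-Lys. The wet-lab screen
amplifies the region and reads the product length; the package reproduces it
computationally. `find_amplicon()` locates the forward primer on the plus
strand and the reverse primer's complement downstream, allowing
`max_mismatch` (default 1) mismatches per site but none in the 3'-terminal
3 bases (a mismatched 3' end does not extend); among the resulting products
it returns the shortest, warning if more than one forms under 2 kb. Fragment
length is end-to-end, both primers included — the convention under which the
published sizes hold: 133 bp without the deletion, 124 bp with it.
`classify_9bp_genotype()` maps lengths to genotypes exactly (tolerance 0);
any other length, or a failed amplification, is `unknown`, a value rather
than an error. mtDNA is circular, but this amplicon does not span the
origin, so the search is linear by default with an opt-in origin window.

Because the package ships no copyrighted reference genome,
`synthetic_mt_reference()` builds a seeded random 16,569-base sequence with
the primer sites and the double repeat implanted at offsets homologous to
the human mtDNA reference frame (forward primer 8196–8217, repeat copies
8272–8280/8281–8289, reverse complement 8307–8328). It is a synthetic
stand-in: only the assay-relevant geometry matches the real reference, so
assay results on it validate the amplicon arithmetic and the screen's logic,
not primer specificity against the true genomic background.

## Pedigree conventions

Pedigrees use a PED-like six-column text format (family, id, father, mother,
sex 1/2, origin), with origin occupying the slot classic PED uses for the
phenotype since no canonical column exists for it. Validation enforces
resolvable references, male fathers, female mothers and acyclicity, with
errors naming the offending row. A *founder* has both parents missing;
`origin` is meaningful for founders. Individuals with one recorded parent
terminate the missing side's uniparental line at themselves — partial
genealogies are the norm in real cohorts — and cohort members without
ancestral links ("new founders") are modelled as founders with
`origin = other`, tracked but binned separately, rather than guessed into a
population.

mtDNA propagates mother-to-child and the Y father-to-son;
`propagate_lineages()` assigns every individual a matriline founder, a
patriline founder (males only) and the corresponding expected haplotypes.
`lineage_concordance()` compares propagated haplotypes with observed calls
after collapsing both to a clade depth, flagging discordant samples as
candidate pedigree errors or unrecognised founders.

## Admixture estimation

The estimand is the pair of ancestry-fraction vectors by founder origin —
maternal over the evaluation subset, paternal over its males with a defined
patriline. The cohort publications never delimit "present-day individuals"
precisely, so the default evaluation subset is the pedigree *leaves*
(no recorded children), with an explicit id list as override. Lineages
terminating in an unlabelled individual count as `unknown` and are never
redistributed, avoiding silent bias. With no eligible males the paternal map
is undefined (`NULL`), deliberately distinct from zero.

Uncertainty uses a percentile bootstrap (default 1000 replicates): seeded
with `set.seed(seed)`, each replicate draws one `sample(n, replace = TRUE)`
of the subset and the 2.5/97.5 percentiles are taken with R's default
quantile type 7. The recipe is part of the contract — an independent loop
with the same seed reproduces the interval bit for bit. The point estimate
always lies inside its interval. `gender_bias_index()` is the signed
maternal-minus-paternal difference for one origin, in [-1, 1].
`admixture_estimate()` bundles fractions, CIs, surviving-lineage counts and
bias indices into a classed object with `print`/`summary`/`coef` methods.

## The simulator and what it emulates

`simulate_pedigree()` is a forward-time generator with non-overlapping
generations: each generation's unmarried adults pair at random and
monogamously, couples draw Poisson offspring, offspring sex is a fair coin,
and configured immigrants enter the pairing pool of their generation as new
founders. The historical record supplies the scenario, not a mating model,
so the model is the simplest one that reproduces matriline/patriline
structure; recombination, overlapping generations, age structure and
selection are out of scope by design.

Defaults encode the founding scenario: 9 European male and 12 Polynesian
female founders; 3 European male immigrants in the first three generations
(the later settlers who married into the community); 11 generations; a
cumulative cap of 1400 individuals, matching the size of the core pedigree
such studies reconstruct. The per-couple offspring mean defaults to 3.0:
couples are limited by the scarcer sex in each generation, so realised
growth is well below `rate/2` per generation, and 3.0 brings the expected
cumulative pedigree near the cap over 11 generations (measured mean ≈ 1260
over 40 seeds, most runs reaching the cap around generation 10). Hitting
the cap is flagged `capped`; dying out before the horizon — a real
possibility for 21 founders — is flagged `extinct`, never silently
truncated.

Founder haplogroups are drawn from origin-specific clade pools on the
reference trees: Polynesian founders' mtDNA lies in clade B4 with
probability 0.9 (the clade's reported predominance among Polynesian
lineages), otherwise among non-B4, non-H tips; European founders draw from
the H tips, and their Y from the F-branch tips (excluding the East
Asian/Oceanic O sub-branch), with a 0.01 probability of the rare African
E1b1a1 outlier — rare-immigrant signal without dominating 9-male cohorts.
Genotyping noise is per-profile: each variant independently dropped with
probability δ and Poisson(μ) private false positives added at unused
positions. On the bundled toy tree the 9-bp deletion token sits on node B4
itself, so with zero noise the deletion screen flags exactly the B4-clade
carriers — one of the invariants the test suite checks.

The bundled trees are ~28-node (mtDNA) and ~21-node (Y) toys covering the
clades the scenario needs (H, the B4 lineage including B4a1a1m and
B4a1a1a14, the F-branch Y clades, E1b1a1). They mirror the published
clade-defining variants where those are stated — B4a1a1m by `151, 1692,
2416`; B4a1a1a14 sharing these plus `6905`, encoded as siblings so the
one-variant difference is exactly the published relationship, with the
reported ambiguity of the 1692-defined clade's placement left as printed —
and use plausible placeholder tokens elsewhere. They are fixtures for
validation, not a substitute for a full Phylotree build.

## Phylogenetics

Profile-level trees use the Hamming distance (symmetric-difference size of
masked variant sets) and neighbor joining; reference-tree figures use
`induced_subtree_newick()`, the minimal subtree spanning chosen haplogroups
with unary unnamed nodes suppressed and, optionally, branch variants as
square-bracket comments (off by default for strict parsers; labels are
emitted unquoted, with Newick-reserved characters replaced by `_`). The
underlying studies name only the tree-drawing toolkit, so the
reconstruction method is this package's choice, and both routes are
exposed. NJ delegates to `ape::nj()` — the standard implementation in the
field — with two-taxon and three-taxon inputs handled by their closed forms
and negative branch lengths clamped to zero with a warning; correctness is
checked against additive-distance recovery (Robinson–Foulds 0) and the
three-taxon closed form rather than against another NJ implementation.

## Pipeline and reproducibility

`run_pipeline()` chains the stages with flat-file handoffs (PED/TSV/JSON/
Newick) so each stage can be re-run in isolation from its on-disk inputs and
audited; tabular outputs carry `#` headers with the seed and a config
fingerprint, and identical configs give byte-identical outputs. Every
stochastic function takes a mandatory seed; derived seeds are small fixed
offsets of it.

## Numerical choices and degenerate inputs

* Score ties: depth, then name — specificity first, then determinism.
* Empty denominators score as 1 (vacuous match), not as an error.
* Fragment-length genotyping is exact; near-misses are `unknown`.
* Deletions apply right-to-left so coordinates never shift under the edit;
  overlapping edits and non-positional tokens are rejected.
* A wildcard substitution applied to a sequence substitutes the transition
  partner of the reference base (the most likely point mutation).
* Bootstrap: percentile, quantile type 7, seed mandatory.
* NJ negative branches clamped at 0 (standard practice, keeps Newick valid).

## Validation scales and limitations

The test suite validates classification self-consistency on the bundled
trees and 100 random trees (≤50 nodes), oracle equivalence on 100 random
noisy instances, propagation against per-member path walking on 50 random
pedigrees (≤2000 members), and end-to-end parameter recovery on 200
noise-free replicates of the default scenario with 1000-replicate bootstrap
intervals — sizes chosen to exercise the asymptotics while keeping a full
run in minutes on one CPU; `scripts/acceptance.R` recomputes the same
quantities from scratch.

What passing these checks shows — and does not. The simulator plants
haplotypes on a known tree and adds independent dropout/false-positive
noise, so recovery results demonstrate internal consistency of the chain
(simulate → profile → call → propagate → estimate), not robustness to the
correlated errors, heteroplasmy, reference bias or phylogenetic uncertainty
of real sequencing data. The toy trees cannot detect mis-classification
between clades they do not contain. The deletion screen validates assay
logic on a synthetic template, not primer behaviour on real genomic
background. And with the default scenario's fully sex-segregated founders
the admixture estimator operates at the boundary (fractions 0 and 1);
intermediate mixtures are exercised only through the configurable origin
pools and random-pedigree tests.
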