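# uniparental

Uniparental-lineage analysis for founder isolates: mtDNA and Y-chromosome
haplogroup classification, in-silico PCR screening for the Polynesian-motif
9-bp deletion, pedigree-based matrilineal/patrilineal lineage tracing, and
estimation of gender-biased admixture — with a forward-time pedigree
simulator so the whole pipeline can be exercised and validated without any
external data.

## The problem

Island populations founded by a handful of ancestors — the archetype being
the Pitcairn/Norfolk Island community descended from European sailors and
Tahitian women — show extreme *gender-biased admixture*: maternal ancestry
(carried by mitochondrial DNA, inherited mother-to-child) and paternal
ancestry (carried by the Y chromosome, father-to-son) come from different
source populations. Quantifying this bias matters for population history and
for disease-gene mapping in such isolates, where substructure must be
modelled. The package provides the analysis chain a study of such an isolate
needs:

1. **Haplogroup classification.** A sample's variant profile (the set of
   differences from the reference sequence) is compared with every node of
   an annotated reference phylogeny (a Phylotree-style mtDNA tree or a
   minimal skeleton Y tree). With `E` the cumulative defining variants on
   the root-to-node path, `O` the observed profile and `M = E ∩ O` (a bare
   position such as `1692` matches any allele there), each node is scored by
   the symmetric Kulczynski measure

   score = ½ ( |M| / |E| + |M| / |O| ),

   a term with an empty denominator counting as 1; the best node wins, ties
   going to the deeper (more specific) clade.
2. **The 9-bp deletion screen.** Haplogroup-B mtDNA — which accounts for the
   overwhelming majority of Polynesian lineages — carries the loss of one
   copy of the CCCCCTCTA tandem repeat in the COII/tRNA-Lys region. The
   package reproduces the fragment-length assay in silico: the published
   primer pair yields a 133-bp product on a non-carrier template and 124 bp
   on a carrier.
3. **Lineage propagation.** Given a pedigree and founder haplogroups, mtDNA
   propagates along mother links and the Y along father links, giving every
   individual a matriline/patriline founder and expected haplotypes, which
   can be checked for concordance against observed calls.
4. **Admixture estimation.** Maternal and paternal ancestry fractions by
   founder origin over an evaluation cohort (by default the pedigree
   leaves), percentile bootstrap confidence intervals, surviving-lineage
   counts, and the gender-bias index (maternal minus paternal fraction).
5. **Simulation.** A seeded forward-time generator emulating the founding
   scenario (9 European male and 12 Polynesian female founders, later male
   immigrants, ~11 non-overlapping generations growing to ~1400
   individuals, configurable genotyping noise) so that every stage above is
   testable end to end.
6. **Phylogenetics.** Hamming distances between profiles with
   neighbor-joining reconstruction, and annotated Newick export of induced
   reference-tree subtrees.

## Worked example

```r
library(uniparental)

mt <- read_reference_tree(uniparental_example("mt_tree.tsv"))
p  <- variant_profile("NI-042", cumulative_variants(mt, "B4a1a1a14"))
call_haplogroup(p, mt)
#> NI-042 -> B4a1a1a14 (score 1.0000; |M|=17 |E|=17 |O|=17)
```

The profile matches all 17 expected variants of the B4a1a1a14 haplotype, so
the score is 1 and the call is exact. Dropping the clade's private `6905`
variant moves the call to the sibling clade B4a1a1m, which shares the
remaining `151, 1692, 2416` motif.

Simulating the founding scenario and estimating admixture:

```r
cfg <- simulation_config(seed = 7)
sim <- simulate_norfolk(cfg)
sim$ped
#> Pedigree: 1400 individuals (682 male / 718 female), 24 founders, 490 leaves

admixture_estimate(sim$assign, sim$ped, reps = 1000, seed = 7)
#> Gender-biased admixture estimate (pedigree leaves, n = 490)
#>   maternal polynesian  100.0%  [100.0%, 100.0%]
#>   paternal european    100.0%  [100.0%, 100.0%]
#>   surviving matrilines: 10; surviving patrilines: 9
#>   gender-bias index (polynesian): +1.000
```

With only Polynesian female and European male founders every matriline is
Polynesian and every patriline European — the bias index attains its +1
bound, the defining signature of this kind of isolate. Two of the twelve
founding matrilines have already died out by generation 11 in this
replicate (10 survive), illustrating founder-lineage loss.

The deletion screen on the bundled synthetic reference:

```r
ref <- synthetic_mt_reference()
run_deletion_assay(c(noncarrier = ref,
                     carrier = apply_variants_to_sequence(ref, "8281-8289d")))
#>    sample_id fragment_length         genotype
#> 1 noncarrier             133  deletion_absent
#> 2    carrier             124 deletion_present
```

An end-to-end run with flat-file handoffs (PED, TSV, JSON, Newick outputs in
`out/`):

```r
run_pipeline(list(outdir = "out", seed = 7,
                  mt_tree = uniparental_example("mt_tree.tsv"),
                  y_tree  = uniparental_example("y_tree.tsv")))
```

A thin command-line wrapper over the same functions ships at
`inst/scripts/uniparental.R` (subcommands `run`, `call`, `assay`,
`propagate`, `estimate`, `tree`).

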