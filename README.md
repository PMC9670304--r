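# ribohybrid

Hybrid diagnosis from additive nuclear marker polymorphisms and plastid
haplotypes.

## The problem

In many plant groups — aquatic plants with reduced morphology in
particular — hybrids cannot be identified reliably in the field. Multicopy
nuclear markers (the ribosomal *ITS* region, the *5S-NTS* spacer) offer a
molecular diagnosis: a hybrid inherits ribotypes from both parents, so its
direct (uncloned) Sanger sequence shows *character additivity* — an IUPAC
ambiguity code at every position where the parental ribotypes differ. A
sample reading `R` (= A+G) exactly where genotype 1 has `A` and genotype 2
has `G`, at every such diagnostic site, is a hybrid of those genotypes.
Plastid spacers (*rpl20–5'rps12*, *trnT–trnL*) are maternally inherited and
identify which parent was the seed parent.

`ribohybrid` implements this workflow as a tested, reusable pipeline for
people doing plant systematics with Sanger data:

- **IUPAC ambiguity algebra** — merging parental states (`A + G = R`) and
  *peak subtraction* (`set(W) \ set(T) = A`), the inverse operation used to
  recover the second parental copy from a direct read and one known parent.
- **Genotype panels** — per-marker consensus references with diagnostic
  sites, pairwise substitution distances, and deduplication of identical
  haplotypes (collapsed before tree building, mapped back afterwards).
- **Classification** of each direct sequence as a pure genotype, an
  intraspecific hybrid, an interspecific hybrid, or novel, by scoring every
  single-genotype and genotype-pair hypothesis at the panel's diagnostic
  sites (strict set equality; extra intra-individual polymorphisms off the
  diagnostic sites are reported but never penalized). Sub-threshold minor
  peaks (default < 30% of signal) are demoted to the major base first.
- **Clone analysis** — assignment of cloned sequences to parental copy
  classes, correction of polymerase errors (unique substitutions in single
  clones not matching a polymorphism of the direct sequence), detection of
  PCR-mediated recombinant (chimeric) clones via informative-site blocks,
  choice of representative clones, and inference of a missing parent by
  peak subtraction.
- **Maternal assignment** from plastid haplotypes, with explicit
  *equivocal* outcomes when both parents share the haplotype, novel
  haplotypes reported as derived from their nearest neighbour,
  cross-marker resolution, and lower bounds on independent hybrid origins
  (distinct maternal species x haplotype combinations; reciprocal crosses
  flagged).
- **Simple indel coding** — each distinct gap range becomes one `A`/`C`/`N`
  presence/absence character appended to the matrix, with NEXUS/PHYLIP
  export for external tree software.
- **A seeded simulator** that generates panels, direct sequences, clone
  sets and plastid haplotypes with full ground truth, so every step of the
  pipeline is validated end to end at desk scale.

## Worked example

```r
library(ribohybrid)

cfg  <- sim_config(seed = 42, n_samples = 12)
coll <- simulate_collection(cfg)   # panels + direct/clone/plastid data
res  <- run_pipeline(coll)
res
#> pipeline_result: 12 samples; 8 pure, 1 intraspecific, 3 interspecific hybrids

head(res$calls_df[res$calls_df$verdict != "pure",
                  c("sample_id", "verdict", "hypothesis", "n_violated")], 4)
#>      sample_id              verdict      hypothesis n_violated
#> s002      s002 intraspecific_hybrid sp3_gt1+sp3_gt2          0
#> s004      s004 interspecific_hybrid sp2_gt1+sp5_gt1          0
#> s007      s007 interspecific_hybrid sp3_gt2+sp6_gt1          0
#> s010      s010 interspecific_hybrid sp2_gt2+sp6_gt1          0

res$maternal[["s004"]]
#> s004 [rpl20-rps12]: assigned -> sp5 (distance 0)

res$summary
#> hybrid_summary:
#>  hybrid_type n_samples n_combinations maternal_counts reciprocal_cross ...
#>    sp2 x sp5         1              1           sp5:1            FALSE
#>    ...
```

Sample `s002` combines the additive signals of genotypes 1 and 2 of
species 3 with zero violated diagnostic sites — an intraspecific hybrid.
`s004` combines genotypes of two species, and its plastid haplotype is
identical to an `sp5` haplotype and distinct from all `sp2` haplotypes, so
`sp5` was the maternal (seed) parent. The summary tabulates hybrid types,
genotype combinations, maternal directions, reciprocal crosses and a lower
bound on independent origins.

Real data enter through `read_fasta()` (pre-aligned, per marker) plus a
metadata TSV (`sample_id`, `species`, `genotype`, `marker`, `role`);
`build_panel()` turns labelled reference samples into the genotype panel. A
thin command-line wrapper with `simulate` / `classify` / `clones` /
`maternal` / `indelcode` subcommands is installed at
`system.file("scripts", "ribohybrid.R", package = "ribohybrid")`.

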