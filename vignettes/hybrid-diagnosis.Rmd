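---
title: "Diagnosing hybrids from additive marker polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing hybrids from additive marker polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribohybrid)
```

## The model

Multicopy nuclear markers such as the ribosomal *ITS* region are usually
homogenized within a species by concerted evolution, so a "pure" sample
shows a single ribotype. A hybrid retains ribotypes of both parents; its
direct Sanger sequence is the superposition of the two copies and shows an
IUPAC ambiguity at every position where they differ. Classification
therefore reduces to set algebra over the IUPAC alphabet: the expected
direct sequence of a hybrid between genotypes $p$ and $q$ is, column-wise,
the symbol whose base set is $\mathrm{set}(p_j) \cup \mathrm{set}(q_j)$,
and *peak subtraction* recovers the second copy as
$\mathrm{set}(d_j) \setminus \mathrm{set}(p_j)$ from the direct read $d$
and a known parent $p$. Both operations are implemented exactly (4-bit
base masks) and tested by full enumeration over the $15 \times 15$ symbol
pairs.

Plastid spacers are assumed strictly maternally inherited, as established
for the pondweed relatives of the plants this workflow was designed
around. The maternal parent of a hybrid is the parent species whose
plastid haplotype the hybrid carries; when both candidate parents share
the haplotype, no direction can be inferred and the call is *equivocal* —
an explicit outcome, not a failure.

## Classification rules

`classify_direct()` scores every single-genotype and unordered-pair
hypothesis against the panel:

- **Diagnostic columns** are those where at least one pair of panel
  genotypes carries different unambiguous, non-gap states. Only these
  columns are scored.
- A column **matches** a hypothesis when the query's base set *equals*
  the expected set. Containment is not accepted: where parents differ as
  A/T, the hybrid must read W; a plain A fails that site. The biological
  rationale is that hybrids retain both parental ribotypes — a missing
  peak is evidence against the hypothesis, to be absorbed (if at all) by
  the explicit `tolerance`, not by a laxer match.
- The hypothesis score is its number of violated diagnostic sites. The
  best hypothesis must score at most `tolerance` (default 0; 1 is useful
  for noisy traces), otherwise the verdict is `novel`.
- At equal qualifying score a single genotype beats a pair (parsimony);
  ties among pairs produce an `ambiguous` verdict listing all tied pairs.
- Ambiguities at non-diagnostic columns are *extra polymorphic sites*:
  reported, never penalized. This mirrors how samples "otherwise identical
  to" a genotype but carrying additional intra-individual polymorphisms
  are treated as that genotype.
- Sites where exactly one hypothesis parent is gapped are not expressible
  in IUPAC; they are flagged indel-polymorphic and excluded from base
  matching. Columns where the query is `N` or gapped carry no evidence and
  are likewise excluded.

When per-site minor-peak fractions are available, ambiguities whose minor
signal falls below `min_minor_fraction` (default 0.30, following the rule
that small additional peaks of up to about 30% of signal are ignored for
the more polymorphism-prone *5S-NTS* marker) are demoted to the major
state before classification. The major base is taken as the modal
unambiguous panel state at that column that is compatible with the
observed ambiguity — the reference state a clean trace of the major copy
would show.

## Clone analysis

Cloned PCR products carry two artefact classes. *Polymerase errors* are
unique substitutions in single clones that do not correspond to a
polymorphism of the direct sequence; they are corrected to the direct
base, and only under exactly those two conditions (uniqueness among
clones, unambiguous direct state), so genuine template variation is never
touched. *Recombinant (chimeric) clones* arise from template switching
during PCR; over the informative sites separating the two parents, a
chimera reads as a block of one parent followed by a block of the other.

`detect_breakpoints()` declares a clone recombinant when its state string
contains at least two blocks of alternating parental identity, each with
at least `min_block = 2` informative sites. A single discordant site is
more parsimoniously one polymerase error than two template switches, so
it is reported as a *suspect site* instead; short runs matching their
flanking blocks are absorbed. A switch within `min_block` sites of either
end of the informative region is observationally indistinguishable from a
parental clone with a sequencing error, so the simulator only generates
chimeras whose breakpoint leaves at least two informative sites on each
side — such clones are what "recombinant clone" can operationally mean.
The block rule is verified against an independent run-enumeration oracle,
exhaustively over all parental state strings up to length 12.

Representatives follow the sampling convention of the underlying
workflow: one clone per recovered parent; two when a parent is
polymorphic among its clones; recombinants never. If one copy class is
missing entirely, the second parent is inferred by peak subtraction from
the direct sequence and tagged as inferred rather than observed. Without
any parental references, clones are clustered de novo (complete linkage
at distance 1) and the two largest clusters taken as putative parents.

## Maternal assignment

`assign_maternal()` computes the distance from the hybrid's plastid
haplotype to every panel haplotype of the two nuclear-determined parent
species. Distance counts disjoint-base-set columns plus one event per
contiguous gap run present in exactly one sequence — a spacer indel is a
single mutational event, not one per column. Distance 0 to one species
assigns it; distance 0 to a haplotype carried by both species is
equivocal; otherwise the haplotype is novel and reported as derived from
its nearest neighbour(s), with no arbitrary tie-breaking. Across markers,
an assigned call wins (conflicting assignments are an explicit `conflict`
state), then derivation from a single species, then equivocal.
`count_independent_origins()` counts distinct (maternal species,
haplotype) tuples per hybrid type — a lower bound, since identical tuples
may still be independent events.

Identical consensus sequences are merged within a species during panel
construction (aliases retained), but deliberately *not* across species: a
haplotype shared between species is the very signal that makes maternal
assignment equivocal and must stay visible under both species.

## Indel coding

`simple_indel_code()` implements simple indel coding: every distinct
maximal gap range becomes one character; a sequence codes `C` when its
gap matches the range exactly, `N` when one of its gaps strictly contains
the range or the range lies in its ragged leading/trailing ends (missing
data, not indel events), and `A` otherwise — including for partially
overlapping gaps with different coordinates, which is what distinguishes
the simple method from complex coding. The implementation is checked
against a brute-force oracle on hundreds of random gapped alignments.
Coded characters are appended to the matrix and exported as NEXUS with
charsets per partition, ready for external tree software; tree inference
itself is out of scope.

## The simulator

`sim_config()` defaults describe the study system the package emulates: a
small genus of hexaploid aquatic plants in two clades (6 species), the
three widespread species carrying several geographically structured
genotypes (7/2/2 plus two monotypic species and one with two genotypes),
genotypes separated by roughly 1–5 substitutions (drawn uniformly, mean
3) and occasionally one short indel (probability 0.15, length 1–6),
species within a clade about 10 substitutions apart, clone sets with
per-base polymerase error 0.002 and chimera probability 0.1, at least 5
clones drawn per sample and more until both copies are seen (cap 20), and
a collection of 200 samples of which 60% are pure, 12% intraspecific and
28% interspecific hybrids — proportions matching a worldwide collection
in which roughly a quarter of accessions are interspecific hybrids.
Marker lengths (700/300/700/1000) approximate the four markers' aligned
lengths. One designated species pair shares its main plastid haplotype,
reproducing the situation where the cross direction cannot be determined.

Two design choices matter for interpretation. Substitutions are drawn
without replacement over columns per lineage, so configured distances
hold *exactly* — `genotype_divergence = list(6L, 1L, 2L, ...)` reproduces
the printed genotype distances of the three widespread species by
construction, which is what the calibration check verifies. And mutation
is uniform Jukes–Cantor-like with no rate heterogeneity: classification
uses only site patterns, never branch lengths, so this simplification is
inert for what the tests measure.

What the simulator does *not* emulate: electropherogram noise and base
calling, within-copy-class polymorphism beyond the optional extra sites,
alignment error (inputs are pre-aligned by construction), three-way
mixtures, and plastid recombination. Passing tests therefore demonstrate
the correctness of the decision rules under clean additivity, not
robustness to miscalled traces — for real data the `tolerance` and
`min_minor_fraction` knobs absorb moderate noise, and the per-site
evidence in every `additivity_call` is meant to be inspected.

## Numerical and degenerate-input choices

- Internal coordinates are 0-based half-open only inside the indel coder
  (`gap_ranges`); all user-facing reports are 1-based columns.
- Consensus ties within a genotype are stored as the IUPAC merge of the
  tied states and flagged, rather than forcing a call.
- Overlapping base sets count as zero substitution distance
  (conservative: an R-carrying sample is compatible with both an A- and a
  G-genotype; this minimizes false hybrid calls).
- Empty alignments, gap-free alignments, single-clone samples (warning,
  no correction possible), zero-hybrid collections and absent markers
  (filled with `N`) are all defined cases with tests.
- Problem sizes in the test suite (200-sample collections, 1,000 clone
  sets, exhaustive enumerations to length 12 / 8 genotypes) were chosen
  as the smallest sizes at which the stochastic rates stabilize.

## Limitations

The classifier is restricted to two copy classes (single genotypes and
unordered pairs); hexaploids could in principle carry more, but direct
traces resolve at most two. Genotypes differing only by indels are not
separable at diagnostic sites. Reproducing published coded-indel counts
or matrix dimensions requires the original manual alignments and is not
promised. The maternal-inheritance assumption itself is taken from the
literature, not tested.
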