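---
title: "Deciding clonal vs field-effect origin of multifocal tumours from multi-sample variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding clonal vs field-effect origin of multifocal tumours from multi-sample variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Synchronous multifocal bladder tumours — several physically separate foci
present at once in one bladder — can arise two ways. Under the **clonal**
hypothesis a single founder clone seeds the other foci (intraluminally or
through the epithelium), so all foci inherit a common set of somatic
mutations, the *trunk*. Under the **field-effect** hypothesis a
carcinogen-exposed epithelium transforms independently at several sites, so
foci share essentially no somatic mutations beyond the patient's germline.

Given exome variant calls for one normal mucosa sample and two or more
tumour samples of the same patient, clonetrace decides between the models by
phylogenetics on binary mutation markers:

1. **High-confidence filtering.** Only variants whose site filter status is
   pass, whose genotype is called in every sample, and whose *called allele*
   is supported by at least `min_reads` (default 4) reads in every sample
   are retained; variants at known population sites (a dbSNP stand-in VCF)
   are excluded by (chrom, pos, alt).
2. **Binary encoding.** Each sample is scored 1 at a marker when its
   genotype carries at least one copy of that alternate allele
   (heterozygous or homozygous) and 0 when homozygous reference.
3. **Sharing partition.** Each marker falls in exactly one class by its
   carrier pattern: germline (`ALL_SHARED`), trunk (`TUMOUR_SHARED`),
   per-tumour private, normal-private, and two mixed "other" classes.
4. **Tree.** Euclidean distances between the binary rows (the square root
   of the count of discordant markers), plus an all-zero "reference"
   pseudo-sample; a BioNJ tree rooted on the reference; bootstrap support
   for each internal edge by resampling marker columns with replacement
   (default 10,000 replicates; UPGMA is run as a concordance check).
5. **Verdict.** The patient is called clonal when the tumour samples are
   monophyletic — a clade excluding the normal sample and the reference —
   which a shared trunk forces; the clade's bootstrap support quantifies
   robustness to marker resampling.

On top of the clonality verdict, the package times APOBEC-type mutagenesis.
Substitutions are classified by strand-collapsed sequence context: only A
and C reference positions are considered, reading G/T sites off the minus
strand, and the 5' neighbour is recorded on the strand carrying the A/C
(minus-strand preceding = complement of the plus-strand following base).
This yields eight dinucleotide classes; `TpC*` (a mutated C preceded by T)
is the APOBEC deaminase hallmark, most specific as `TpC*pA` in
trinucleotide context. Because trunk mutations are ancestral and private
mutations recent, comparing the TpC* proportion of trunk vs private markers
(Fisher's exact test, ratio of proportions) reads out *when* APOBEC was
active: a high trunk-to-private fold means early activity.

## BioNJ, rooting, bootstrap

BioNJ is a variance-weighted neighbour joining suited to heterogeneous
branch lengths (tumour lineages accumulate many more variants than the
normal lineage). Starting from distances $d$ and variances $v = d$, the pair
$(i,j)$ minimising $Q(i,j) = (r-2)\,d_{ij} - S_i - S_j$ is joined
($S_i=\sum_k d_{ik}$), with pendant lengths
$b_i = d_{ij}/2 + (S_i-S_j)/(2(r-2))$, $b_j = d_{ij} - b_i$, and the
reduction
$d_{uk} = \lambda d_{ik} + (1-\lambda) d_{jk} - \lambda b_i -
(1-\lambda) b_j$, $v_{uk} = \lambda v_{ik} + (1-\lambda) v_{jk} -
\lambda(1-\lambda) v_{ij}$, where
$\lambda = 1/2 + \sum_k (v_{jk}-v_{ik}) / (2(r-2)v_{ij})$ clamped to
$[0,1]$; the final three taxa are joined exactly.

Numerical choices:

* **Tie-break.** Equal $Q$ values are resolved on the lowest $(i,j)$ index
  pair, making the output (and the whole bootstrap, given a seed)
  deterministic.
* **Negative branch lengths** are retained in stored trees; they preserve
  additivity diagnostics and are standard NJ practice.
* **Support is attached to bipartitions**, not node labels, so values are
  invariant to rooting and to sample order. The bootstrap resamples *all*
  matrix columns, germline-shared ones included; a flag-free design was
  preferred because germline columns are constant across real samples and
  only dilute, never bias, split frequencies relative to the reference row.
* On any additive distance matrix the implementation recovers the
  generating tree exactly (patristic distances reproduce the input to
  1e-9); the test suite verifies this on 1,000 random trees of 4–8 taxa
  against a topology-enumeration + least-squares oracle and against
  independent NJ/BioNJ implementations.

## Contamination checks

A "normal" sample containing neoplastic cells masquerades as a shared
ancestor: trunk variants leak into it and are reclassified as germline.
Three criteria each raise a warning flag: (a) the normal leaf falls inside
the smallest clade containing all tumours; (b) the normal terminal branch
is at least as long as the shortest tumour terminal branch; (c) the
tumour-associated fraction of markers falls below 0.20 (a contaminated
patient can drop to ~15 %, against ~40 % for clean ones).

Criterion (b) is evaluated on a companion tree built from *squared*
Euclidean (Hamming) distances. On that scale distances are additive in
marker counts for this data structure, so terminal branches count
lineage-specific variants (normal-private ≈ 3 vs the smallest tumour
private set ≈ 15 at default scales). On the square-root display scale
branch lengths are not additive and the normal terminal is systematically
inflated, which would make (b) fire on clean patients. Note that in
simulations, heavy contamination typically leaves tumour monophyly intact
(the normal attaches along the trunk edge), so detection rests chiefly on
criterion (c) — the same signature that identifies a contaminated patient
in practice. The tumour-associated-fraction criterion presumes a clonal
context; genuine field-effect patients also have low fractions and will
carry the flag, which should then be read together with the non-monophyly
verdict.

## The exact 2x2 test

All group comparisons (functional enrichment trunk vs germline; TpC* trunk
vs germline; TpC* trunk vs pooled private) use a two-sided Fisher exact
test: conditioning on the margins, the (1,1) cell is hypergeometric, and
the p-value sums the probabilities of all tables whose point probability is
at most the observed one, with a relative slack of 1e-7 absorbing
floating-point ties (the minimum-likelihood rule of `fisher.test`, which
serves as an independent cross-check in the tests, alongside an exhaustive
enumeration oracle covering every table with total ≤ 30). Folds are ratios
of proportions — the only reading consistent with unequal set sizes — with
no pseudocounts: an empty denominator yields `Inf`, flagged rather than
smoothed. The handful of planned comparisons are reported without
multiplicity correction. The private set in the timing contrast pools
private markers across tumours; per-tumour counts are available from the
partition table.

## What the generator emulates — and what it does not

`sim_config()` defaults define one synthetic patient at the scale of a real
multifocal bladder exome study: 900 germline markers, a 450-marker trunk,
private sets of 40/25/15 across three tumours, 12 + 12 mixed-class markers
and 3 normal-private markers (~1,457 high-confidence markers in all);
planted TpC* fractions 0.10 (germline), 0.60 (trunk), 0.20 (private);
functional fractions 0.20 (germline) vs 0.40 (trunk/private). These choices
reproduce the qualitative behaviour of interest — 100 % tumour-clade
bootstrap support under the clonal model, a ~6-fold trunk/germline TpC*
enrichment, a ~3-fold trunk/private timing contrast, and a ~2-fold
functional enrichment. The genome model is two 100-kb contigs of
independent bases at GC 0.41 (roughly exomic); markers are placed on sites
whose strand-collapsed context matches their planted class, so the context
classifier can be validated marker by marker. A field-model patient has no
trunk; a contaminated patient leaks a configurable fraction of trunk
markers into the normal sample. One seed drives a single RNG stream, so
emitted FASTA/VCF/truth files are byte-reproducible.

The depth model draws DP from a Poisson around `mean_depth` floored at 12,
and het alt reads binomially, clamped into [6, DP−6]: at zero `dropout`
no planted genotype can fall under the 4-read filter, which is what makes
the zero-noise round trip (pipeline output ≡ truth) exact rather than
probabilistic. `dropout` instead plants 0–3-read genotype entries to
exercise the filter. Deliberately *not* modelled: read-level errors and
mapping artefacts, copy-number changes, subclonal allele fractions,
realistic linkage between neighbouring sites, indel realism (indels pass
through the pipeline as generic markers), and transcript-level annotation
(ANN strings encode planted tiers directly). Passing tests therefore
demonstrate the correctness of the *analysis* under its stated model, not
robustness to every failure mode of real exome calls.

Scales used by the test suite: the acceptance checks run the generator
defaults with 1,000 bootstrap replicates (and 100 replicates across the
50-seed model-discrimination sweep); unit tests use reduced class sizes.
These sizes were chosen so the full suite exercises full study-scale
behaviour while remaining quick to run routinely.

## Open choices made here

* **"Supported by ≥ 4 reads in all samples"** is read as reads supporting
  the *called* allele (alt AD for carriers, ref AD for homozygous
  reference, DP fallback). Requiring alt-supporting reads in all samples
  would delete every somatic marker (hom-ref samples have alt depth 0), and
  total depth ignores the genotype actually asserted.
* Records with any missing genotype are dropped, not imputed.
* Multi-allelic rows are split per alternate allele; a sample scores 1 only
  for the allele its genotype contains. Known-site exclusion matches the
  specific alt, so somatic alleles coincident with common SNP positions
  survive.
* A site's impact tier is the maximum severity across transcript
  annotations; variants annotated to several genes are reported once per
  gene in the driver overlap (losslessness over deduplication).
* All six sharing classes are reported separately rather than aggregating
  the mixed classes into a single "other" bar.
* `UNKNOWN` contexts (contig edges, N neighbours, non-SNV markers) are
  excluded from context denominators and reported as counts.

## Limitations

Clonality is inferred from presence/absence of variants only: allele
fractions, copy number and subclonal structure are out of scope, as are
likelihood-based phylogenetics and clock models. The bootstrap quantifies
resampling stability, not calling error. With two tumour samples the
monophyly question degenerates (two sisters are always a cherry), so the
verdict then rests on the trunk size and support values rather than
topology alone.
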