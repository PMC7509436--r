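---
title: "Haplotype-based fingerprinting: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based fingerprinting: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The setting

Clonally propagated crops circulate as grafted copies: the same genotype
appears under many names (synonyms), and named "new" cultivars are often
bud sports — somatic mutants differing from their parent clone at a single
locus, typically by loss of heterozygosity (LOH). A fingerprinting system
for such a collection must (i) genotype cheaply and reproducibly, (ii)
separate clones from genuinely distinct genotypes, and (iii) quantify how
many individuals — including close relatives — the marker set can tell
apart.

`haplofinger` works with *segments*: short PCR amplicons (roughly 430–720
bp) containing several SNPs each, genotyped by Sanger sequencing. The SNP
haplotype within an amplicon is the segment's allele, so every segment is
one multi-allelic locus; a diploid genotype is an unordered pair of
haplotype IDs per segment. Segments are placed on different
chromosomes/scaffolds, so they are treated as unlinked, and all multi-locus
probabilities are products of per-segment terms. Phase *between* segments
is never used, which is why pairs are stored in canonical (sorted) order.

## Heterozygote calling from peak traces

A Sanger chromatograph position is called heterozygous when the secondary
peak is a different base and its signal exceeds a fixed fraction of the
primary signal; the call is the two-base IUPAC code. The threshold is
`0.50` for single-copy amplicons. Four segments amplify two near-identical
adjacent genomic copies with one primer pair; these are genotyped as one
composite diploid locus, and because a variant present in one of four gene
copies produces a proportionally weaker secondary peak, their threshold is
relaxed to `0.30`. The comparison is strict (`ratio > threshold`): a tie at
exactly the threshold stays homozygous. Lowering the threshold can only
convert homozygous calls to heterozygous ones, never the reverse — a
monotonicity property the test suite asserts on random traces.

Signals are taken as already-normalised linear intensities; no baseline
correction or mobility normalisation is applied. Manual exclusion of
poor-quality chromatograph regions is supported through an explicit
per-position `mask` argument (masked positions become `N`) rather than an
invented quality heuristic. Binary trace formats (AB1/SCF) are out of
scope; the package consumes tabular peak traces.

## SNP extraction

Each aligned consensus symbol expands to an unordered allele pair (`A` →
A/A, `R` → A/G, …). A column is a SNP site iff at least two distinct bases
occur among non-missing samples. `N`, gaps, and three-base ambiguity codes
(`B/D/H/V`) are missing — a diploid cannot carry three alleles, so such
symbols are upstream noise. Columns with gaps in more than half the
samples are skipped outright; the intended amplicons are indel-free, so
this rule only guards degenerate inputs.

## Haplotype phasing by EM

Within one segment, unphased multi-SNP genotypes are phased by
gene-counting EM on haplotype frequencies. A genotype vector with $h$
heterozygous sites is compatible with $\max(1, 2^{h-1})$ unordered
haplotype pairs. With frequencies $p$, the E-step weights each compatible
pair $(h_1, h_2)$ of individual $i$ by $c\,p_{h_1} p_{h_2}$ ($c = 2$ when
$h_1 \ne h_2$), normalised within the individual; the M-step sets $p$ to
the expected haplotype counts over $2N$ gene copies. The log-likelihood is
asserted non-decreasing at every iteration, and iteration stops when the
largest absolute frequency change drops below `tol` (default `1e-8`).

Determinism was a design goal — an MCMC sampler would make every downstream
ID assignment run-dependent. A subtlety, discovered on a three-individual
test instance, is that the natural deterministic choice (uniform
initialisation over the compatible haplotypes) can be a *stationary saddle*:
when the two pairings of a double heterozygote have exactly tied weights at
the start, gene counting preserves the tie forever, and the run converges
up to 0.5 log-likelihood units below the global maximum. `em_phase`
therefore runs the uniform start plus 10 Dirichlet-jittered restarts drawn
from a fixed internal seed (the session RNG is saved and restored), keeping
the best likelihood. The procedure is still a pure function of its inputs;
`restarts = 0` reproduces plain uniform-start EM. On small instances
(≤ 3 heterozygous sites, ≤ 6 individuals) the test suite checks the
converged likelihood against an independent multi-start Nelder–Mead
maximisation of the same likelihood to within `1e-6`, and on 500 simulated
diploids from six skewed haplotypes the estimated frequencies must land
within 0.03 of truth.

Remaining conventions: equally likely phase configurations resolve to the
lexicographically smallest pair; haplotype IDs are assigned `1..k` in
descending frequency with lexicographic tie-break; individuals missing the
segment are excluded from that segment's estimation and left unphased
there; enumeration refuses vectors with more than 20 heterozygous sites
(amplicons this heterozygous indicate an upstream problem, and $2^{19}$
pairs would be pointless to weight).

## Diversity statistics

With per-segment haplotype frequencies $p_i$ estimated from $n$ gene
copies (two per non-missing diploid):

- haplotype diversity $H_d = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$
  (the unbiased form is the default; the biased form $1 - \sum p_i^2$ is a
  flag — at $n \ge 144$ copies the difference is below two printed
  decimals);
- observed heterozygosity $H_o$ = fraction of typed diploids with two
  distinct haplotype IDs;
- $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$.

`summarize_segments(..., on_collapsed = TRUE)` recomputes frequencies over
distinct genotypes only (one copy per clone group); clone-family sizes
otherwise dominate the frequency estimates. Column means are unweighted
across segments.

## Identity and discrimination capacity

Under Hardy–Weinberg equilibrium at one segment, with $S_k = \sum_i p_i^k$:

$$\mathrm{PI} = S_4 + \sum_{i<j} (2 p_i p_j)^2 = 2S_2^2 - S_4, \qquad
\mathrm{PI_{sib}} = \tfrac14 + \tfrac12 S_2 + \tfrac12 S_2^2 - \tfrac14 S_4.$$

Per observed genotype, the probability that a random individual / a parent
or offspring / a full sibling carries the identical genotype is, for a
homozygote $(i,i)$: $p_i^2$, $p_i$, $((1+p_i)/2)^2$; for a heterozygote
$(i,j)$: $2p_ip_j$, $(p_i+p_j)/2$, $(1+p_i+p_j+2p_ip_j)/4$. The
parent–offspring homozygote value $p_i$ reads: the parent certainly
transmitted $i$ and matches iff its second allele is also $i$. All these
formulas are verified in the tests against genotype-pair enumeration
oracles (Mendelian transmission enumerated over all parent genotype
classes) to `1e-12`, and their HWE expectations must reproduce PI and
PI_sib exactly. Multi-locus values multiply across segments.

The *discrimination capacity* converts a cumulative PI into a population
size: the largest $n$ such that the expected number of identical pairs
$\binom{n}{2}\,\mathrm{PI}$ stays at or below $\alpha = 0.05$ — a birthday
bound. $\alpha$ is an argument, not a constant.

`minimal_marker_set` finds **all** minimum-cardinality segment subsets that
separate every distinct genotype, by exact search over subset sizes in
increasing order (segments pre-sorted by descending PIC so informative
subsets are met early, with a product-of-per-segment-genotype-counts upper
bound as prune). Greedy-only search would return one subset and miss
equally minimal alternatives, which matter in practice when a segment
amplifies poorly in some material.

## Clones, somatic mutants and parentage

The differential segment number (DSN) between two profiles is the count of
segments at which their canonical pairs differ (missing segments skipped,
the skipped count reported alongside). DSN 0 is a clone or synonym; DSN in
`1..somatic_threshold` is the somatic-variant tier; the default threshold
of 3 reflects collections where confirmed bud sports differ at one segment
(LOH) while distinct genotypes differ at four or more — it is an argument,
not a constant. DSN is a count pseudo-metric (symmetric, triangle
inequality), asserted on random panels.

A pair of distinct genotypes above the somatic tier is a candidate
parent–offspring pair iff the two genotypes share at least one haplotype
at *every* segment — the exact Mendelian necessary condition for unlinked
loci without genotyping error. The candidate network is an undirected
graph (direction is unknowable from genotypes alone). Chance sharing makes
this rule conservative in the false-positive direction; no
likelihood-based assignment (LOD scores) is attempted.

Parentage non-exclusion probabilities — that a random unrelated candidate
is *not* excluded as one parent (other parent known), as a single parent
(no parent known), or as a parent pair — are computed by exact enumeration
over HWE genotype classes and Mendelian transmissions, not by transcribing
literature closed forms; transcription of those long polynomials is a
classic error source, so the Jamieson–Taylor closed forms appear only in
the test suite, where enumeration must match them to `1e-10` for up to six
alleles. The scenario ordering (parent pair ≤ one parent known ≤ no parent
known) is asserted on 100 random frequency vectors, and across $10^4$
simulated trios a true parent is never excluded. Cumulative non-exclusion
across segments is the product of per-locus values.

## Distance, trees, ordination, core sets

The simple-matching distance averages per-segment dissimilarity
$1 - m/2$, where $m \in \{0,1,2\}$ is the multiset overlap of the two
haplotype pairs; `m/2` multiplicity counting is the stated convention for
heterozygote-versus-homozygote comparisons. UPGMA is average-linkage
`hclust` (ultrametric by construction, asserted to `1e-9`); NJ is `ape`'s
Saitou–Nei implementation, with negative branch lengths clamped to zero
and the deficit moved to the sister edge so path lengths through the
parent are preserved — NJ on additive matrices is required to be exact in
the tests. Bootstrap support resamples *segments* with replacement
(segments, not SNPs, are the unit of the distance), recomputes the tree,
and counts matching leaf bipartitions; runs are deterministic given a
seed. PCoA is Gower double-centering via `cmdscale`; axes with negative
eigenvalues (possible, since the distance is non-Euclidean) are dropped
from both the coordinates and the explained-variance denominator.

Core sets maximise allele coverage: the fraction of distinct
(segment, haplotype) pairs present in the selected genotypes. The
optimiser is greedy seeding (largest coverage gain, first-index
tie-break) followed by steepest-ascent single-swap exchange, repeated from
200 seeded random restarts by default; the tests require it to match
brute-force enumeration for panels of 20 genotypes and subset sizes up to
4. No exact metaheuristic schedule of any particular core-selection tool
is reproduced.

## The synthetic generator

`sim_config()` defaults describe the study conditions the package is built
around: 19 segments with the reference panel's per-segment SNP and
haplotype counts (148 haplotypes total, mean 7.8 per segment, four
segments marked two-copy), Dirichlet concentration 0.3 — which yields one
common haplotype plus a tail of rares and a mean minor-allele frequency
near 8–9% — 72 base genotypes expanded to 141 accessions with clone-family
sizes `18, 14, 3×18, 2×3, 1×49` (the two large families mirror the most
widely propagated cultivars; the remainder is the simplest split of the
published 49-singleton / 23-repeated structure), one planted LOH pair and
10 planted trios. Base genotypes are HWE draws from the segment
frequencies; offspring are Mendelian; LOH converts one heterozygous
segment to homozygous. Truth tables (template membership, somatic events,
trio links, generating frequencies) are first-class outputs, and
every recovery test compares against them, never against re-derived state.

What the generator does *not* emulate: genotyping error and allelic
dropout (peak noise is truncated Gaussian on signal intensities only),
indels and alignment error (amplicons are indel-free by design),
within-segment recombination, population structure or inbreeding
(Hardy–Weinberg throughout), and linkage between segments. Passing
end-to-end tests therefore certify the algorithmic chain, not robustness
to those real-data pathologies. Peak traces are emitted for the forward
strand only; with indel-free amplicons a reverse read adds no information.

## Numerical conventions and degenerate inputs

Frequencies must be positive and sum to 1 within `1e-9`; distance matrices
symmetric within `1e-12` with an exactly zero diagonal. Genotype tables
must be complete rectangles (a missing amplicon is a fully missing
segment genotype, never a half-missing pair). Genotype collapse orders
groups by descending size, then first-accession order. All coordinates are
1-based, the R convention. Capacity returns at least 1 (with PI = 1 no
pair is safe). The parent-pair enumeration refuses loci with more than 40
alleles.

Problem sizes in the test suite — chosen so the whole suite runs in well
under a minute while still exercising every property: phasing oracle
instances of 3–6 individuals; frequency recovery at $N = 500$; identity
oracles at $k \le 5$; exclusion oracles at $k \le 6$ plus 100 ordering
draws; $10^4$ trio exclusions; $10^5$ genotype-pair identity draws;
end-to-end studies of 3–19 segments and 10–141 accessions.

## Known limitations

- Duplicated two-copy segments are modelled as a single composite diploid
  locus; how four physical gene copies collapse into two sequenced
  haplotypes is not modelled beyond the relaxed calling threshold.
- Candidate parent–offspring detection is exact-sharing and breaks under
  genotyping error; the non-exclusion machinery quantifies random
  false-positives, not error-induced false-negatives.
- Within-segment SNP density per kilobase is reported but depends on the
  length denominator convention; panel-level totals are the certified
  quantities.
- No model-based population-structure inference is provided; clustering
  and PCoA are descriptive.
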