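---
title: "Models and methods behind lionpanel"
author: "lionpanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lionpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lionpanel)
```

## Scope

`lionpanel` implements the genotyping workflow used to survey population
structure across the lion's range: starting from low-coverage whole-genome
SNP calls for a small discovery cohort, it masks and filters the calls,
designs a small diagnostic panel of autosomal and mitochondrial SNPs, and
then analyses a large panel-genotyped cohort — sample QC, mitochondrial
haplogroup assignment with confidence grading, supervised clade assignment,
PCA, an allele-sharing dendrogram, observed heterozygosity and the
ABBA-BABA D-statistic. Because real resequencing data are not required for
validating the machinery, the package ships a structured-population
simulator whose outputs exercise every stage.

## The synthetic population model

The simulator uses a hierarchical Balding–Nichols model. An ancestral
allele frequency $p$ is drawn uniformly from a minor-allele range (default
0.1–0.5, random orientation, reflecting SNP-discovery ascertainment in a
small cohort). Each subspecies frequency is drawn from
$\mathrm{Beta}\big(p\,\tfrac{1-F_s}{F_s},\,(1-p)\tfrac{1-F_s}{F_s}\big)$,
which has mean $p$ and variance $F_s\,p(1-p)$; clade frequencies are drawn
the same way around their subspecies frequency with per-clade drift $F_c$.
The default coefficients are $F_s = 0.15$ for the basal northern/southern
split and $F_c = 0.05$ for each clade, except the India clade at
$F_c = 0.30$: the Indian population has passed through severe bottlenecks
and consistently shows the lowest diversity, and a high drift coefficient
is the simplest way to encode that. $F = 0$ is handled as the no-drift
limit (the frequency is copied); $F = 1$ is rejected.

An individual with admixture proportions $q$ over the four clades carries
an alt-allele dose drawn from $\mathrm{Binomial}(2, \sum_c q_c p_c)$. A
diverged outgroup lineage ("Tiger") is drawn around the ancestral frequency
with $F = 0.5$; it stands in for the reference-genome species in four-taxon
tests.

Sequencing is emulated per cell: depth $d \sim \mathrm{Poisson}(\lambda_i)$
with a per-sample mean $\lambda_i$; $d = 0$ yields a missing call. A true
heterozygote with $d \ge 1$ is observed heterozygous only when both alleles
appear among $d$ uniform allele draws, i.e. with probability $1 - 2^{1-d}$,
otherwise it is called homozygous for the sampled allele — classic allelic
dropout. Homozygotes are observed as-is. With depth-$\ge m$ masking the
expected observed/true heterozygosity ratio has the closed form
$\mathbb{E}[1 - 2^{1-d} \mid d \ge m]$, implemented in
`het_dropout_factor()` and used as a quantitative oracle in the tests.

The **discovery preset** (`discovery_config()`) mirrors the study design:
ten genomes named after their sampling populations — Benin, Cameroon, DRC
(West & Central Africa), India, Somalia, Kenya (East Africa), Zambia1,
Zambia2, RSA, Namibia (Southern Africa) — at mean depth 3.8x overall, with
Benin fixed at 0.5x (the very-low-coverage sample) and Kenya deepest. The
per-sample depths are package choices; only the cohort mean, the Benin
value and the ordering are anchored. 5,000 unlinked sites across 400
scaffolds (mapped round-robin onto the 18 felid autosomes) keep the preset
fast while leaving hundreds of panel-eligible candidates.

The **cohort preset** (`simulate_cohort()`) emulates a 211-sample
panel-genotyped cohort: four clades, ten admixed individuals with ancestry
split evenly between East Africa and West & Central Africa (the
Ethiopia/Kenya contact-zone analogue; the study gives no quantitative
admixture proportions, so $q = 0.5/0.5$ is a free parameter), and forty
poor-quality samples whose per-call assay failure rate (0.35 autosomal,
0.30 mitochondrial) pushes them past the 25% missingness cutoff; the
remaining samples fail at 8% per autosomal call (median ~10 missing SNPs
of 125) and 2% per mitochondrial call.

Mitochondrial variation follows a six-haplogroup key (West Africa, Central
Africa, North East Africa, East/Southern Africa, South West Africa, India).
The model holds three candidate private diagnostic sites per haplogroup
plus four candidate subspecies-diagnostic sites whose derived allele is
shared by the northern haplogroups. Numts — nuclear copies of mitochondrial
segments — are emitted as decoy records: segments of the synthetic
mitogenome (16,756 bp) mutated at a configurable per-base divergence
(default 8%, inside the range where an assay flank still aligns well).

What the generator does **not** emulate: linkage and recombination (sites
are unlinked, so block bootstraps are unnecessary on synthetic data even
though they matter for real genomes), base-calling error, mapping artefacts
(the mapping-quality criterion is exercised through supplied summary stats,
not simulated reads), reference bias, and realistic site-frequency spectra.
Passing tests therefore validate the statistical machinery and its
thresholds, not robustness to alignment-level artefacts.

## Filtering

Masking follows the ambiguous-nucleotide convention: any call with
per-sample depth below 3 becomes missing, cell-wise (a provenance flag
distinguishes masked cells from input-missing ones). Whether the original
procedure dropped whole sites or cells is not fully explicit; cell-wise is
the reading consistent with per-individual ambiguity replacement, and sites
are only dropped by the ladder. The missing-data ladder retains sites
called in at least 1, 3, 5, 8, or all samples; surviving counts are
non-increasing by construction and the canonical order is mask-then-filter.
Chromosome attribution maps scaffolds through a scaffold-to-chromosome
table (in the study, the tiger genomic architecture); unmapped scaffolds
are labeled `unplaced`.

## Panel design

Autosomal candidates pass six criteria: (1) minimum combined depth of 20
across all samples at every position of the 101-nt window — the strictest
defensible reading of "across 50 bp upstream and downstream"; a
mean-over-window alternative is a one-line change but the minimum is what
an assay-design engineer would want; (2) at most one additional variable
position, by default counted across both flanks jointly (conservative; a
per-flank reading is available via `per_flank = TRUE`); (3) a
mapping-quality proxy — the original by-eye browser inspection is not
reproducible, so the package accepts per-site soft-clip fractions and
indel distances and passes candidates through with an `unassessed` flag
when no stats are supplied; (4) at least eight individuals called at the
site; (5) at most one SNP per scaffold with chromosomes filled round-robin
(the even-spreading rule is underdetermined by the source procedure — the
scaffold cap is stated, the spreading rule is this package's and is
isolated in `select_autosomal_panel()`); (6) all-heterozygote sites are
excluded as likely collapsed duplications, and sites showing both
heterozygous and homozygous calls earn a scoring bonus.

Scoring and tie-breaking are package inventions required for determinism:
score = number of called samples + composition bonus; within a scaffold and
within a chromosome, ties break by ascending position (then scaffold).
Identical inputs give byte-identical panels.

Mitochondrial selection keeps, for each haplogroup, its best candidate
diagnostic sites, plus exactly two subspecies-diagnostic sites, to the
target of 14; every selected flank must survive numt screening — a local
(Smith–Waterman) alignment against each numt with risk declared when an
alignment covers the focal position at $\ge 80\%$ identity over $\ge 40$
columns. An empty numt set passes with an `unscreened` flag rather than
silently asserting safety.

## Assignment

Samples with more than 25% missing autosomal panel calls are excluded
(strict inequality, so 31/125 missing is retained and 32/125 is excluded).

Haplogroup calls are graded purely by call rate and key matching: with
call rate $r$ over the 14 mtDNA SNPs, $r < 60\%$ (equivalently $\ge 40\%$
failed) yields no assignment ('?'); $60\% \le r \le 85\%$ yields the
best-matching haplogroup with a qualified grade; $r > 85\%$ a confident
one. Both band edges are inclusive; with 14 SNPs the two band definitions
never conflict because $k/14$ cannot land on 0.60. The best match
maximizes agreement over called SNPs; contradicting calls are counted as
conflicts, and ties are reported jointly and force the qualified grade
(the original matching rule is unstated; this one is deliberately simple
and exhaustively tested over all $2^{14}$ missingness masks).

Clade assignment is supervised: the unsupervised clustering used in the
study consistently recovered the four known clades, so the package
estimates pseudocount-smoothed reference allele frequencies per clade
(from retained samples of known origin) and scores each sample by the sum
of log Hardy–Weinberg genotype probabilities, normalizing to a posterior
under a uniform prior. Missing SNPs are skipped; a pseudocount of 1 keeps
frequencies strictly inside (0, 1).

One caveat is documented deliberately: a pure-clade likelihood model
cannot simultaneously assign pure samples with posterior > 0.9 and leave
*most* 50/50 admixed samples below that threshold. For small per-SNP
effects the log-likelihood-ratio sum has variance close to twice its mean,
so any panel informative enough for decisive pure-sample assignment makes
the admixed sample's zero-mean ratio wander far from zero. Admixed samples
are still markedly less confidently assigned (several-fold more of them
fall below 0.9 than pure samples, and their mean posterior is visibly
depressed), and that is the property the test suite asserts.
Detecting intermediate ancestry *per se* requires an admixture-aware model
(continuous $q$), which is out of scope.

PCA mean-imputes missing cells per SNP, centers, scales, and fixes each
component's sign so its largest-magnitude loading is positive. The
dendrogram uses allele-sharing distance $d = 1 - $ mean sharing over
jointly called SNPs (1 for identical genotypes, 0.5 for het vs hom, 0 for
opposite homozygotes) and neighbor-joining; trees serialize to newick.

## Heterozygosity and the D-statistic

Observed heterozygosity is heterozygous calls over scored calls, per
individual; at the population level it is computed on panel SNPs called in
at least five members of the population and averaged over qualifying SNPs.
Under the preset drift hierarchy expected heterozygosity scales with
$2p(1-p)(1-F_s)(1-F_c)$, so the bottlenecked India clade sits lowest — a
property the acceptance suite checks on the cohort preset.

The D-statistic uses the frequency form: with group alt-frequencies
$p_1, p_2, p_3, p_4$ at a usable site (all four groups called),

$$D = \frac{\sum (1-p_1)p_2p_3(1-p_4) - p_1(1-p_2)p_3(1-p_4)}
           {\sum (1-p_1)p_2p_3(1-p_4) + p_1(1-p_2)p_3(1-p_4)},$$

so single diploid genomes and multi-genome groups share one code path.
Significance comes from resampling sites (optionally consecutive-site
blocks) with replacement: $Z = D/\mathrm{sd}(D^\ast)$, significant at
$|Z| \ge 3$ (the conventional threshold; configurable). The outgroup
enters only through $p_4$; there is no separate ancestral-recoding step.
1,000 bootstrap replicates are the headline default.

**Problem sizes for the replicate suites.** The calibration suite runs 200
no-admixture replicates of the discovery preset with the clade-based
groups (P1 = the four Southern Africa genomes, P2 = the two East Africa
genomes, P3 = the three West & Central Africa genomes, outgroup = Tiger);
under the hierarchy P1 and P2 are exchangeable with respect to P3, so
$\mathbb{E}[D] = 0$ and the false-positive rate at $|Z| \ge 3$ stays in
the percent range. The power suite injects gene flow from the P3 clade
into every P2 sample (migrant fraction 0.3 at 20% of sites), which shifts
$D$ by only $\approx +0.02$. Detecting an effect of that size at
$|Z| \ge 3$ is a genuine sample-size question: with one genome per group —
the discovery-cohort situation — genotype-sampling noise dominates and
detection would need several hundred thousand sites, which is why
`simulate_dstat_study()` uses a designed experiment of 20 genomes per
clade at 40,000 unlinked sites, fixed by power analysis before the suite
was frozen. The replicate suites use 100
bootstrap replicates per test, which estimates $Z$ to within a few
percent; single showcase runs keep the full 1,000.

## Numerical choices and degenerate inputs

Beta draws are clamped away from exact 0/1 so downstream binomials stay
defined near fixation. Monomorphic sites contribute zero to both D-stat
sums; a fully zero denominator flags the result as undefined rather than
returning NaN. Zero-variance SNPs are dropped before PCA; samples with
zero scored sites are an error for heterozygosity, as are pairs with no
jointly called SNPs for the distance matrix (such samples should have been
QC-excluded). Every generator is deterministic under its seed, and
bootstrap replicates are reproducible under the `seed` argument.

## Known limitations

Sites are unlinked, so real-data linkage (which inflates D-statistic
variance and motivates block bootstraps) is only available through the
`block` argument, not the generator. The mapping-quality criterion is a
proxy; with no auxiliary stats it is a documented pass-through. The
supervised assigner presumes the reference clades are the right model
space — it reports *which* clade fits best, with honest uncertainty, but
is not an admixture estimator. The simulator's effect sizes (drift
coefficients, assay failure rates) are plausible for the system but are
not fitted to data.
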