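---
title: "Relative haplotype dosage NIPT with population-based parental haplotyping"
author: "hapdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative haplotype dosage NIPT with population-based parental haplotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdose)
```

## The problem

Noninvasive prenatal testing (NIPT) of recessive monogenic disease asks, for
each parent, *which of that parent's two haplotypes did the fetus inherit?*
Cell-free DNA (cfDNA) in maternal plasma is a mixture: a fraction $1-f$ of
fragments derive from the mother's two haplotypes and a fraction $f$ (the
*fetal fraction*, typically 5–25% in the first trimester) from the two fetal
haplotypes. A single pathogenic site rarely carries enough reads to decide
maternal inheritance against the overwhelming maternal background, but the
*haplotype* carrying the variant drags along many linked SNPs, and across
those SNPs the inherited haplotype is consistently over-represented. This is
relative haplotype dosage (RHDO) analysis. It needs phased parental
haplotypes, and the distinctive choice here is to obtain them from a
*population reference panel* built from carrier-screening data
(population-based haplotyping, PBH) rather than from additional family
members (family-based haplotyping, FBH) or molecular phasing. α- and
β-thalassemia are the prototype application: recessive, common in southern
China, and genetically mixed (SNVs, small indels, and large deletions such
as --SEA carried as copy-number variants).

## Pipeline and model

### Reference panel

`filterPanelSnps()` applies two per-site quality rules to the cohort before
phasing, removing a site when (a) more than 2% of samples cover it below
20×, or (b) more than 70% of its heterozygotes show an alt-allele ratio
inside the closed band [5%, 40%] — a signature of systematic allelic
dropout or mapping bias. Design choices where the filter could reasonably
be defined either way, resolved here: the two rules are combined by OR
(either suffices to remove a site); the skew band is applied to the alt
allele only, not also to its mirror image [60%, 95%]; missing
genotypes count in the depth-rule denominator but not in the het-ratio
denominator; CNV pseudo-sites are exempt from the ratio rule, whose
read-ratio premise does not hold across a deletion.

CNVs ride through every downstream step disguised as biallelic pseudo-SNPs
(`encodeCnvAsSnp()`): position = CNV start, genotype 0/1 or 1/1 for
heterozygous/homozygous carriers, with the true interval kept in an
INFO-style `KIND=CNV;CNVEND=` annotation. Two CNVs starting at the same
position must carry distinct alt labels to remain distinguishable — the
encoding is otherwise ambiguous, a documented limitation.

### Phasing

In production settings panel phasing is usually delegated to a dedicated
large-panel phaser such as Beagle; an external Java binary cannot be a test
dependency, so the phaser here is pluggable: any pre-phased VCF is accepted
(`readPhasedVcf()`), and the built-in reference implementation is a diploid
haplotype-copying model (`phaseWithPanel()`).
The hidden state at site $j$ is the ordered pair $(x_j, y_j)$ of panel
haplotypes being copied; each coordinate independently jumps to a uniformly
chosen haplotype with probability $1 - e^{-\rho d}$ per interval of $d$ bp,
with $\rho = 4 N_e c / H$, $c = 10^{-8}$ per bp, default $N_e = 10^4$, $H$
the panel haplotype count — configuration, not science. Emissions compare
the implied dosage $h_{x_j} + h_{y_j}$ with the observed genotype through a
per-allele mismatch probability (default 0.005). Joint Viterbi decoding over
ordered pairs is exact and $O(S H^2)$ because the stay/jump transition
structure factorizes the maximization; ties resolve toward the smaller
haplotype index, making output deterministic. For panels above
`maxPanelHaps` (default 400) haplotypes, the state space is first restricted
to the haplotypes most compatible with the sample's homozygous sites — the
composite-reference device used by all large-panel phasers; the cap is a
tunable and `Inf` disables it. Phase at a heterozygous site where the
decoded pair is uninformative (both copied haplotypes agree) is assigned
deterministically (hap1 keeps the first copied haplotype's allele); output
is genotype-consistent at every site by construction.

`phaseTrio()` implements FBH for comparison: Mendelian transmission fixes
phase except at triple-heterozygous sites, which stay unphased;
inconsistent sites are flagged and excluded. `haplotypeConcordance()`
scores two phasings over commonly phased heterozygous sites after choosing
the global orientation (identity or swap) that maximizes agreement — the
orientation convention is this package's choice, since per-parent
concordance can only be defined up to haplotype labeling.

### Informative SNPs, in two steps

Paternal inheritance is decoded first, on sites heterozygous in the father
and homozygous in the mother: there the paternal-specific allele is either
present at frequency $f/2$ or absent, and the maternal background is flat.
Maternal inheritance is decoded second, on (type 1) sites heterozygous in
the mother and homozygous in the father, plus (type 2) double-heterozygous
sites inside genomic blocks whose paternal transmission the first step
resolved — there the known paternal contribution shifts the expected ratio
and the maternal hypotheses separate again. A paternal block is "resolved"
when every site in it holds a forward–backward posterior at or above the
confidence threshold; partial blocks qualify. Sites inside any CNV carried
by *either* parent are excluded from both steps — the conservative scope
for the exclusion, since the plasma ratio inside a deletion is distorted
regardless of which parent carries it — as are sites off the target's
chromosome, CNV pseudo-sites
themselves, and sites with missing or unphased parental genotypes.

### Fetal fraction

At sites where the parents are opposite homozygotes the fetus is an
obligate heterozygote and the paternal-specific allele sits at plasma
frequency $f/2$. There is no single canonical formula for f from targeted
counts; `estimateFetalFraction()` implements the standard pooled estimator
$\hat f = 2 \sum_i k_i / \sum_i n_i$ over usable sites ($k_i$
fetal-specific reads, $n_i$ depth), clamped to $[0, 0.5]$, with a per-site
median variant available for robustness comparisons; the pooled form is the
default for low-depth stability. Sequencing error is deliberately *not*
subtracted here — it is modeled in the HMM emissions, and subtracting it
twice would bias the dosage test. Fewer than `minSites` (default 10) usable
sites raises an explicit "not estimable" error, distinct from an estimate
of zero.

### Dosage HMM

Per parent, the hidden state over that parent's informative SNPs is which
haplotype the fetus inherited: HAP_P (carrying the target's pathogenic
variant) or HAP_N. The expected plasma alt fraction under each hypothesis
follows from copy counting — maternal haplotypes weigh $(1-f)/2$ each,
fetal haplotypes $f/2$ each (`expectedAltFraction()`). Emissions are
binomial in read counts with the per-read error rate $\varepsilon$ (default
0.005) folded symmetrically into the mean,
$\mu' = \mu(1-\varepsilon) + (1-\mu)\varepsilon$; a beta-binomial
overdispersion knob exists but is off by default, binomial being adequate
for the simulated data and the cleanest depth-aware choice. Transitions
flip state with probability $\tfrac12 (1 - e^{-2 r d})$ over $d$ bp at rate
$r = 1.2\times10^{-8}$ per bp — physical distance, no genetic map, because
the target regions are tens of kb and map resolution is immaterial at that
scale. Decoding is Viterbi (ties toward HAP_N: prefer the normal haplotype
when the data cannot decide), with forward–backward posteriors computed
alongside; everything is in log space.

### Confidence and no-calls

Blocks are maximal runs of the Viterbi state. A block's core interval runs
from its first to its last informative site; extended intervals reach to
the midpoints between adjacent blocks and to ±∞ at the outer ends. The
confidence score (CS) is the forward–backward posterior of the decoded
state at the informative site nearest the target, within the spanning
block — anchored, not block-averaged, because the score must describe the
call *at the pathogenic locus*. An allele is reported no-call when CS falls
below 0.99 or when the path holds two or more blocks and none of their core
intervals contains the target midpoint (a recombination breakpoint too
close to the gene); a single block always calls, whatever its extent, since
one inherited segment then covers the whole region. Zero informative sites
give CS = 0 and a no-call, never a crash. A parent who is not a simple
heterozygous carrier at the target needs no decoding — homozygous-pathogenic
forces a pathogenic call, non-carrier forces normal, both at CS 1 and
flagged `uninformative-by-genotype`. The supporting-SNP counts reported per
haplotype tally per-site maximum-likelihood support (which emission wins at
each site); counting Viterbi-path membership instead would be the other
defensible convention, and the per-site reading is the one implemented.

### Classification and referral

`classifyFetus()` maps the two allele calls to
normal / carrier / affected / partial (one no-call) / failed (two
no-calls). Invasive diagnosis is recommended for affected fetuses, for
partial results whose called allele is pathogenic, and — conservatively,
as nothing was excluded — for failed results; the failed case does not
occur in the packaged cohort and the convention is flagged here.
`summarizeCohort()` tabulates per-allele concordance against invasive
results (no-calls never enter the denominator; per-allele, not per-fetus,
matching how the accounting is usually reported), with a Clopper–Pearson
95% interval from `binom.test()`. The mean fetal fraction is displayed to
one decimal; the raw value stays in the object.

## The simulator: what it emulates, and what it does not

`simulatePanel()` builds a carrier-screening-like panel by founder copying:
marker allele frequencies are drawn from Beta(0.8, 0.8) truncated to
[0.05, 0.95] (a capture design enriched for informative heterozygotes);
each haplotype copies a mosaic of 12 founder haplotypes with per-bp switch
rate $5\times10^{-6}$ (LD decaying over the 200 kb region) and per-site
mutation 0.005; each pathogenic variant rides its own founder whose copying
weight equals the variant's haplotype frequency (default 0.10, appropriate
for a screen-positive-enriched cohort), so carriers share a founder
background. The defaults — 500 panel samples, 220 region SNPs over 200 kb
around the β-globin locus (hg19 coordinates), plasma depth log-normal
around 177×, parental gDNA around 203×, fetal fraction 0.15 (cohort-scale
averages), error 0.005 — are the study conditions and yield 30–60
informative SNPs per parent, the scale seen in practice. Families are fresh
copying realizations from the same population process (not panel members),
each parent conditioned by rejection to carry a pathogenic variant;
fetuses receive one recombined haplotype per parent (Poisson breakpoints at
$1.2\times10^{-8}$ per bp — essentially zero over 200 kb, as in reality).
A separate backbone of 200 unlinked common SNPs (MAF 0.2–0.5, independent
parental genotypes) is simulated for fetal-fraction estimation, mirroring
the polymorphic-marker backbones cfDNA assays carry for exactly this
purpose; within a founder-structured 200 kb region alone, opposite
homozygotes are too rare ($\mathbb E[q^2(1-q)^2] \approx 0.03$ per site)
to support the estimate.

What the simulator does *not* reproduce: alignment and genotype-calling
errors in the parents (genotypes are true; only depths are noisy),
GC-dependent coverage structure, fragment-length differences between fetal
and maternal cfDNA, maternal mosaicism, and real LD patterns beyond the
founder-mosaic approximation. Passing the end-to-end tests therefore
certifies the inferential machinery under the stated statistical model, not
performance on real sequencing data.

## Numerical choices and degenerate inputs

All HMM arithmetic is in log space; forward–backward columns are normalized
by log-sum-exp and checked to sum to one within $10^{-9}$. Viterbi ties
break toward HAP_N in the dosage HMM and toward the smaller index in the
phasing HMM — both deterministic. Zero-depth sites contribute zero
log-likelihood symmetrically; missing AD fields are recorded as zero depth
and excluded from ratio computations rather than imputed. Multi-allelic
records are rejected, not split. Empty informative-site sets, empty panels
and fewer-than-minimum FF sites raise typed errors or produce CS = 0
no-calls as documented above. Coordinates are 1-based inclusive everywhere;
BED input is converted on read.

## Problem sizes used by the checks

The shipped checks run the pipeline end-to-end on 200 simulated families
(100 in the acceptance script) against the 500-sample default panel, the
panel-size experiment on 25 families × 6 subsampling levels × 3 replicates
from a 300-sample panel, and oracle comparisons by exhaustive enumeration
up to $2^{12}$ dosage paths and $H^{2S}$ copying paths for small $H, S$ —
sizes chosen so the whole suite completes in minutes on one core while
keeping every estimate's Monte-Carlo error well inside the asserted margins.

## Known limitations

- The fetal-fraction estimator, the HMM parameterization and the CS
  definition involve choices on which practice varies between labs; this
  package fixes one defensible version of each and exposes every constant
  in `hmmConfig()` / `simConfig()`.
- The built-in phaser is a faithful but minimal Li–Stephens-type
  implementation, not a Beagle replacement; for production use, phase
  externally and load via `readPhasedVcf()`.
- Overlapping CNVs sharing a start position need distinct alt labels.
- The invasive-referral rule for failed (double no-call) fetuses is a
  convention (refer), not an observed case.

## A worked example

```{r example, eval = FALSE}
cfg <- simConfig(plasmaDepth = 200)
panel <- simulatePanel(cfg, seed = 42)
target <- defaultTarget(cfg)
fam <- simulateFamily(panel, cfg, seed = 7)
counts <- simulateCfdna(fam$mother, fam$fetus, cfg, seed = 8)
run <- runFamilyNipt(fam, counts, panel, target)
run$result$maternal
run$result$paternal
classifyFetus(run$result$maternal, run$result$paternal)

## cohort accounting of the packaged 59-family table
tab <- readCohortTable(system.file("extdata", "thalassemia_cohort.tsv",
                                   package = "hapdose"))
summarizeCohort(tab)
```
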