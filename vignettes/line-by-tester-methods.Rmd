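---
title: "Line x tester combining ability, heterotic grouping and SNP diversity: methods"
author: "testcross package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Line x tester methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(testcross)
```

# Scope and model

`testcross` analyses multi-environment line x tester trials of the kind
used to characterise maize inbred lines against tester lines of known
heterotic group, optionally under parasitic-weed (*Striga hermonthica*)
infestation, and to cross-check the resulting heterotic groups against a
SNP panel. The trial side assumes the linear model

$$
y_{ijker} = \mu + E_e + R_{r(e)} + B_{b(re)} + g_i + g_j + s_{ij}
          + (gE)_{ie} + (gE)_{je} + (sE)_{ije} + \varepsilon_{ijker}
$$

for the plot value of the cross between line $i$ and tester $j$ in
environment $e$ (a location-year), replicate $r$ and incomplete block $b$:
hybrids are fixed, environments and all terms involving them random. The
ANOVA is sequential (type I) in the canonical order Environment,
Rep(Env), Block(Env x Rep), Hybrid — partitioned into Line (GCA), Tester
(GCA), Line x Tester (SCA) — the matching environment interactions, and
Error. Checks and the tester-cross entry are excluded before the hybrid
degrees of freedom are partitioned. F ratios for the genetic terms use the
corresponding x Environment mean square when fitted, otherwise the error
mean square; Environment is tested against Rep(Env).

Effects come from raw testcross cell means (not BLUEs), which makes the
centering identities exact in balanced data: line and tester GCA each sum
to zero, SCA rows and columns sum to zero, and with two testers the tester
GCAs are equal and opposite. HSGCA for a line with a tester is
$g_i + s_{ij}$, equivalently the testcross mean minus that tester's mean.
Standard errors are the Kempthorne forms
$\mathrm{SE}(g_\mathrm{line}) = \sqrt{MSE/(ret)}$,
$\mathrm{SE}(g_\mathrm{tester}) = \sqrt{MSE/(rel)}$,
$\mathrm{SE}(s) = \sqrt{MSE/(re)}$, with two-sided t tests on the error
degrees of freedom.

## Incomplete blocks and the intrablock caveat

The alpha-lattice adjustment is a sequential block-within-rep term — the
same partition the trial reports print — not a recovery-of-interblock-
information lattice analysis. A consequence worth knowing: when incomplete
blocks are fitted before the hybrids, the intrablock genetic mean squares
are scaled by the design's efficiency factor (roughly $v(k-1)/(k(v-1))$
for $v$ entries in blocks of $k$, about 0.77 for 44 entries in blocks of
4). Variance components estimated from a lattice trial therefore carry
that attenuation; the package's parameter-recovery experiment runs on a
complete-block layout, where the method-of-moments estimators are exactly
unbiased (verified to within ~1% over 200 replicates at $l=20$, $t=2$,
$e=4$, $r=2$).

## Variance components, heritability, repeatability

Components come from equating observed to expected mean squares (method of
moments), which is exact for balanced designs and fully reproducible;
REML could sit behind the same contract but is not required for the
balanced core:

$$
\hat\sigma^2_{SCA} = \frac{MS_{lt} - MS_{lte}}{re},\quad
\hat\sigma^2_{GCA(L)} = \frac{MS_l - MS_{le}}{ret},\quad
\hat\sigma^2_{GCA(T)} = \frac{MS_t - MS_{te}}{rel},
$$

with interaction components $(MS_{le}-MSE)/(rt)$, $(MS_{te}-MSE)/(rl)$ and
$(MS_{lte}-MSE)/r$ — the divisors under which the GCA estimators above are
unbiased. Negative solutions are truncated at zero and flagged, which
keeps $h^2$ and repeatability inside $[0,1]$.

Both parents are inbred lines, so with parental inbreeding coefficient $F$
(default 1, exposed as an argument because the conversion is the least
standardised step in this literature):

$$
\sigma^2_A = \frac{4}{1+F}\left(\sigma^2_{GCA(L)} + \sigma^2_{GCA(T)}\right),
\qquad
\sigma^2_D = \frac{4}{(1+F)^2}\,\sigma^2_{SCA},
$$

reducing at $F=1$ to $2(\sigma^2_{GCA(L)}+\sigma^2_{GCA(T)})$ and
$\sigma^2_{SCA}$. Narrow-sense heritability on an entry-mean basis is
$h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_D + \sigma^2_{GE}/e +
\sigma^2_\varepsilon/(re))$, and entry-mean repeatability is
$R = \sigma^2_H/(\sigma^2_H + \sigma^2_{HE}/e + \sigma^2_\varepsilon/(re))$
with $\sigma^2_H = (MS_H - MS_{HE})/(re)$.

# Heterosis and heterotic grouping

Standard heterosis is $H = 100\,(F_1 - CK)/CK$ with $CK$ the mean of the
hybrid between the two testers; infestation yield loss is
$100\,(y_{non} - y_{inf})/y_{non}$.

Two classifiers assign lines to the heterotic groups HGA (represented by
tester 1) and HGB (tester 2). Combining well with a tester places a line
in the *opposite* group, so evidence with tester 1 assigns HGB and vice
versa — a fixed mapping, never inferred from data.

**SCA + yield.** A line is assigned when its SCA with the favourable
tester exceeds a threshold (default 100 kg/ha, meaningful for grain yield
only), its SCA with the other tester is negative, and its testcross mean
is not significantly below the tester-cross mean. The yield gate uses
$LSD = t_{1-\alpha/2,\,df_e}\sqrt{2\,MSE/(re)}$ because the underlying
trial reports state only "not significantly different" without naming a
test; both the gate's $\alpha$ and the SCA threshold are arguments. With
two testers the centering identity makes the two SCA sign conditions one
test; the classifier still checks both.

**HSGCA.** Positive HSGCA with tester 1 assigns HGB, positive with tester
2 assigns HGA. When both values share a sign, the published rule — keep
the group with "the smallest positive or the largest negative" value — is
ambiguous about "largest negative". The default `tie_rule = "min_value"`
reads it as *most negative*, collapsing the clause into "the tester with
the smaller HSGCA decides"; `"max_value"` implements the closest-to-zero
alternative. A dead-zone `epsilon` (default 0) around zero lets near-zero
evidence produce "not classified" calls, since published group tables do
contain unclassified lines that a strict sign rule could not produce.

Consensus across conditions (infested, non-infested, across all
location-years) is the unanimous non-unassigned call; disagreement is
reported as `inconsistent`, and coverage (how many conditions produced a
call) is attached.

# Marker module

QC retains markers with missing fraction $\le$ 0.10, major allele
frequency $\le$ 0.95 and observed heterozygosity $\le$ 0.20 — conjunctive
criteria, so filtering is order-independent. "MAF" here is deliberately
spelled out as *major* allele frequency in the report, because the same
acronym is often read as minor.

Per marker over non-missing calls: gene diversity $1 - p^2 - q^2$
(at most 0.5 for a biallelic SNP) and Botstein's
$PIC = 1 - (p^2+q^2) - 2p^2q^2$ (at most 0.375). Chromosome and panel
summaries are unweighted means.

Two distances are computed and labelled, because published genetic-
distance tables rarely say which convention produced them:

* **Jaccard** on allele-presence bits (dosage 0 gives \{A\}, 1 gives
  \{A,B\}, 2 gives \{B\}): $1 - |I|/|U|$ over markers co-called in both
  samples. Jaccard is undefined on raw dosages; the bit expansion is the
  dominant convention, and a shared-genotype variant is available behind
  a flag.
* **IBS**: $1 - \text{shared alleles}/(2 \cdot \text{co-called})$, with
  shared alleles per marker $2 - |d_1 - d_2|$.

Missing data are handled pairwise-complete for distances; the only
imputation in the package is marker-mean fill inside PCA. Ward clustering
uses the `ward.D2` convention (dissimilarities squared inside the
Lance-Williams update), named in the output because the `ward.D`/`ward.D2`
choice changes trees. The number of clusters is chosen by maximal mean
silhouette width over Ward cuts, ties broken toward the smallest k. PCA
reports percent variance as eigenvalue over trace on the centered
(optionally scaled) matrix, so the percentages sum to 100.

# The synthetic-data generators

Every stage is testable without external data because both generators
return complete truth tables.

**Trial generator.** Defaults emulate a 24-line x 2-tester factorial plus
four checks (tester-cross, tolerant, susceptible, resistant) in a 13 x 4
alpha-lattice with 2 replications, 4 infested and 6 non-infested
location-years. The non-infested grand mean is 5,300 kg/ha with plot error
variance $10^6$ (CV ~19%), and the genetic and G x E variance defaults
(96,000 / 380,000 / 49,000 / 150,000 / 60,000 / 50,000 kg²/ha²) are of the
magnitude implied by published multi-environment testcross trials of this
type. Main effects and SCA are drawn iid and centered within factor
(SCA double-centered); G x E draws are centered within environment. This
makes the estimator identities exact in the noise-free limit while keeping
the method-of-moments estimators unbiased, because the ANOVA sums of
squares carry the same degrees of freedom either way.

Under infestation each plot receives a damage score (latent normal,
shifted against line GCA, discretised and clamped to the 1-9 scale) that
drives a multiplicative yield loss through a logistic link calibrated
through two points: damage 8 loses 80% and damage 4 loses 31%, which
places a tolerant check (damage ~6.1) near 59% and a resistant commercial
check (damage ~4.7) near 40%. Emerged-parasite counts are negative
binomial with mean tied to $-g_i$; the distributional form is a stand-in —
field counts are only known to be overdispersed — and its dispersion is a
config knob. One integer seed drives named sub-streams (`trial`,
`genotypes`), so sub-experiments are independently reproducible.

With the realistic defaults the attainable correlation between estimated
and true line GCA is bounded by $\sqrt{\sigma^2_g/(\sigma^2_g + V)}$ with
$V$ the G x E plus plot-error variance of a line mean (~0.77 at $e=6$);
the tests assert recovery against that bound, and exact recovery in the
noise-free limit.

**SNP panel generator.** Defaults emulate a two-ancestral-population
inbred panel: 26 samples (populations of 6 and 20), 3,305 biallelic
markers on 10 chromosomes, Balding-Nichols population frequencies around
ancestral frequencies uniform on (0.2, 0.8) with divergence 0.25, residual
heterozygosity 0.04, 2% missing calls. Designated markers violate exactly
one QC criterion each (600 missing-data, 500 major-AF, 152
heterozygosity), and clean markers are rejection-sampled to pass all
three filters, so exactly 2,053 markers survive QC by construction and
the filter's truth is auditable. Clustering-recovery experiments use
divergence 0.45 ("high divergence"); the default stays 0.25.

What the generators do *not* emulate: linkage and genetic maps, pedigree
structure, genotype-phenotype coupling (the trial and marker streams are
independent), spatial field trend, and non-normal plot-error
distributions. Passing tests therefore demonstrate estimator correctness
and pipeline integrity under the stated model, not robustness to
violations of it.

# Numerical choices and degenerate inputs

* Sequential sums of squares are computed through pivoted-QR least
  squares on accumulated indicator matrices, so rank-deficient
  (unbalanced) cores degrade to least squares on available data with a
  warning and a `balanced = FALSE` flag, rather than failing.
* Missing plot values are an explicit sentinel (`NA`), never zero; all
  estimators skip them and report effective n.
* Negative variance components truncate to zero with a flag.
* Single-environment inputs drop the interaction rows with a message and
  test genetic terms against error.
* All-equal (zero-variance) trait data yield zero effects, not `NaN`.
* Distance pairs with no co-called markers are `NA` with a warning;
  clustering refuses incomplete matrices instead of silently imputing.
* Silhouette ties break toward the smallest k; candidates with $k \ge n$
  are skipped with a note.
* Ordinal damage scores (1-9) and parasite counts are analysed
  untransformed, as trial reports conventionally present them; a
  log(x+1) transform for counts can be applied upstream if desired.

# Problem sizes

The test suite and the acceptance script run entirely on generated data:
the default 24 x 2 trial is 1,040 plots over 10 environments; the
parameter-recovery experiment uses 200 replicate trials of 320 plots; the
marker experiments use the 3,305-marker default panel plus 600-800-marker
panels for clustering recovery. These sizes keep a full run in tens of
seconds on one CPU while leaving Monte-Carlo error well inside the
asserted tolerances.

# Known limitations

* No interblock-information recovery for the lattice (see the efficiency
  factor caveat above) and no spatial/AR1 modelling.
* No BLUP/stage-wise analysis; effects are cell-mean based by design.
* No admixture-model fitting: population-structure membership is out of
  scope, and the conventional 60% membership threshold is applied only if
  an externally produced Q-matrix is supplied.
* No LD pruning, kinship matrices, or imputation beyond PCA mean-fill.
* Mid-parent/better-parent heterosis is out of scope (parents per se are
  not evaluated in a testcross trial).
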