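---
title: "Mapping liver-fibrosis QTLs and candidate-gene networks in RI panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping liver-fibrosis QTLs and candidate-gene networks in RI panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroqtl)
```

## The analysis this package implements

Recombinant inbred (RI) panels such as the BXD set — fully inbred lines
descended from an F2 intercross of C57BL/6J (B) and DBA/2J (D) — allow a
quantitative trait to be measured on many genetically identical animals
per genome. `fibroqtl` implements the complete funnel used to dissect
toxin-induced liver fibrosis in such a panel:

1. animal-level fibrosis phenotypes (hydroxyproline, collagen area,
   histological F-score, serum ALT) are collapsed to per-line, per-sex
   summaries after outlier trimming, and heritability is estimated from
   one-way ANOVA variance components;
2. each trait is genome-scanned by Haley–Knott regression on expected
   allele dosage, with permutation-derived genome-wide thresholds,
   composite interval mapping (CIM) and 1.5-LOD support intervals,
   yielding phenotype QTLs (pQTLs);
3. strain-level expression of every transcript is scanned the same way
   (eQTLs), peaks are classified cis or trans by a 10-Mb rule, and each
   pQTL support interval is dissected into counts of genes, regulatory
   markers, cisQTLs and cis-regulated genes (cisQTGs);
4. cisQTGs are filtered by three criteria — correlation with a fibrosis
   trait, a segregating non-synonymous SNP, and differential
   cis-regulation between treated and control livers — into a tiered
   candidate list;
5. candidate genes are joined into a signed co-expression network and a
   signed permutation-p QTL heatmap.

A synthetic RI-panel generator with planted truth backs every stage, so
the whole pipeline is testable against known answers.

## The mapping model

At a genome position with expected allele dosage $x_i \in [-1, +1]$
(B homozygote $-1$, D homozygote $+1$) and per-line trait values $y_i$,
the scan fits

$$ y_i = \mu + \beta x_i + \varepsilon_i $$

by least squares and reports the likelihood ratio statistic

$$ \mathrm{LRS} = n \,\ln\!\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1},
   \qquad \mathrm{LOD} = \frac{\mathrm{LRS}}{2 \ln 10} \approx
   \frac{\mathrm{LRS}}{4.605}, $$

where the reduced model holds the intercept (and, under CIM, the
covariate-marker dosages) only. The slope $\beta$ is the *additive
allele effect*: positive values mean the D allele increases the trait.
Heterozygous and unknown calls are treated as missing — RI lines are
modelled as fully inbred — and lines missing a dosage are dropped
position-wise; positions with fewer than 8 usable lines are flagged
rather than silently skipped.

### Dosages between markers

Pseudomarkers are inserted every `step_cM` (default 1 cM). A cM
distance $d$ is converted to a meiotic recombination fraction by the
Haldane map function $r = (1 - e^{-2d/100})/2$ (no interference), and
then expanded to the RI-line transition probability for sib-mated
panels,

$$ R = \frac{4r}{1 + 6r}, $$

the Haldane–Waddington expansion. (The selfing formula $2r/(1+2r)$
would be wrong for BXD-style panels.) The dosage at a pseudomarker is
the conditional expectation of the allele given the flanking genotypes
under the two-interval Markov chain; with one informative flank it is
$g\,(1 - 2R)$.

### Thresholds and intervals

Genome-wide significance is calibrated by permuting the strain labels
of the trait vector (genotypes fixed; default 2,000 permutations,
seeded). The 95th percentile of the permuted genome-wide maximum LRS is
the *significant* threshold ($p_G = 0.05$); the 37th percentile is the
*suggestive* threshold ($p_G = 0.63$, the one-false-positive-per-scan
convention — by construction roughly 63% of null scans contain at least
one suggestive excursion, which is why suggestive loci are reported but
never interpreted alone). Support intervals are the widest contiguous
region in which LOD stays within 1.5 of the peak, with linear
interpolation of the crossing points and clipping at chromosome ends.
Tied peaks resolve to the smaller Mb coordinate; this is recorded in
run provenance. The two parental strains can be included as mapping
lines (the default), matching how such panels are usually analyzed.

### Heritability

Variance components come from one-way ANOVA by the method of moments:
$V_w = \mathrm{MS}_{within}$ and
$V_b = (\mathrm{MS}_{between} - \mathrm{MS}_{within})/n_0$ with $n_0$
the unbalanced-design average group size; negative $V_b$ estimates are
clamped to zero and flagged. Heritability is reported as the intraclass
ratio $h^2 = V_b/(V_b + V_w)$, which is bounded in $[0,1]$. A literal
ratio of between- to within-strain variance would exceed 1 for highly
heritable traits; the intraclass form is what reported values in the
0.5–0.6 range imply, so it is the one implemented.

## Expression normalization and the eQTL funnel

Each strain's array is Z-scored with the population (divide-by-$n$) SD,
multiplied by 2 and shifted by 8, so every array has mean exactly 8 and
SD exactly 2; one unit then corresponds to roughly a two-fold
expression change. The population-SD convention makes the transform
exactly idempotent on tiny test arrays; the procedure is otherwise
standard practice for this data type.

An eQTL is *cis* when its peak lies on the gene's chromosome within
10 Mb of the gene start, *inclusive* at exactly 10 Mb (the boundary
convention is declared here because prose rules rarely state it).
"Gene position" means the transcript start; "genes in a pQTL region"
means gene start inside the closed support interval (the genome-browser
convention; overlap-based membership would count partially overlapping
genes and is not used). Regulatory markers are counted as *distinct*
peak positions — whether a marker shared by several transcripts should
count once or repeatedly is ambiguous in published tables whose row
sums disagree with their printed totals; distinct counting is the
declared choice, and the packaged fixture tables keep rows and printed
totals separate rather than reconciling them.

## Candidate criteria

* **Criterion i** — |Pearson r| strictly greater than 0.36 between the
  gene's strain-level expression and any of the three fibrosis traits
  (collagen area, hydroxyproline, F-score; ALT is excluded). 0.36 is
  the two-sided $p = 0.05$ critical value at 30 strains
  (`critical_r(30)`). No multiple-testing correction is applied across
  genes — the funnel is an explorative screen and the output records
  this.
* **Criterion ii** — the gene carries a non-synonymous SNP segregating
  between the parental strains (annotation lookup).
* **Criterion iii** — differential cis-regulation, implemented as the
  XOR of cis status across the treated and control datasets: cis in
  exactly one condition is class A (flag true), cis in both is class B.
  Whether cis-in-control-only should count as class A cannot be decided
  from published class counts; the XOR (conservative-inclusion) form is
  the default and the treated-only variant is a one-line change in user
  code.

The census (tier ≥ 1 / ≥ 2 / = 3) is monotone by construction, mirroring
the genes-in-regions → cisQTGs → candidates chain.

## Network and heatmap

Candidate-gene edges keep $|r| > 0.36$ (strict), classed strong above
0.5, and scoped intra-/inter-chromosomal; node connectivity counts
inter-chromosomal edges only, matching the convention of drawing only
inter-chromosomal correlations in circular network figures. Unsigned
degree is used — counting signed edges separately is possible but not
the default. The heatmap encodes each position as
$\mathrm{sign}(\beta)\,(-\log_{10} p)$ with $p$ the add-one-smoothed
genome-wide permutation p-value, floored at $1/(n_{perm}+1)$
(default 1,000 permutations), so a cell can never be infinite and the
sign convention matches the additive-effect convention.

## What the synthetic generator emulates — and what it does not

`simulate_ri_genotypes()` draws each line as an independent Markov
chain along each chromosome with flip probability $R$ per interval;
the default map has 19 autosomes of 70 cM with markers every 2 cM and
2 Mb per cM, a deliberately mouse-like density. Phenotypes are
`strain genetic value + shared strain residual + within-strain noise`,
scaled so the intraclass ratio equals the target $h^2$ in expectation
and so each planted QTL explains its stated fraction of the
*strain-mean* variance ($V_b + V_w/m$ for $m$ replicates); sex-scoped
effects apply to one sex only, which leaves the unaffected sex slightly
less variable between strains. Expression is baseline + planted marker
effects + Gaussian strain-level noise, per condition.

The generator deliberately does **not** emulate: epistasis beyond
two-locus products, genotyping error, X-chromosome dosage, non-Gaussian
residuals (the real traits are skewed and the F-score is ordinal), or
correlated expression noise (real arrays share batch structure).
Passing tests on synthetic data therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to
real-data pathologies.

## Numerical choices and degenerate inputs

* Constant traits or monomorphic positions give LRS 0, not NaN.
* A dosage collinear with CIM covariates (e.g. scanning the covariate
  marker itself) gives LRS 0 — the self-conditioning sanity check.
* $r^2$ is capped at $1 - 10^{-12}$ before the log.
* Outlier trimming is the Tukey $1.5 \cdot \mathrm{IQR}$ box-plot rule,
  the reproducible operationalization of trimming "after graphical
  inspection"; groups of three or fewer values are never trimmed.
* Strain means (not medians) feed the scans by default; medians are one
  argument away, since either may be appropriate per trait.
* All generators take explicit integer seeds; the pipeline derives
  per-stage sub-seeds deterministically from the config seed.

## Validation scale and a known power limitation

The test suite validates the machinery at deliberately compact problem
sizes (panels of 20–35 lines, 4–5 chromosome maps, 120–300
permutations, 100–200 simulation replicates), and the acceptance script
re-runs the key checks at study scale (35 lines plus parents, the full
19-chromosome map, 1,000–2,000 permutations). These sizes are the
package's validation choices and are stated here so results are read at
the scale that produced them.

One honest limitation deserves emphasis: with ~35 lines, a locus
explaining 30% of strain-mean variance has an expected LRS of only
about 13, comparable to the genome-wide null maximum of a mouse-sized
map. Under these conditions the genome-wide scan peak lands within
10 Mb of the true locus in roughly 60–80% of simulations (the
acceptance script reports the measured rate), even though the effect
*sign* at the true locus is essentially always recovered. Support
intervals spanning 10–25 Mb, not point localization, are the honest
resolution of an RI panel of this size — which is exactly why the
downstream funnel dissects whole support intervals rather than single
peak markers.

## A worked miniature

```{r example, eval = FALSE}
library(fibroqtl)

map <- ri_map_spec(n_chr = 5, length_cM = 60, spacing_cM = 3)
geno <- add_parents(simulate_ri_genotypes(35, map, seed = 1))
pheno <- simulate_phenotypes(geno, list(planted_qtl("c3_m011", 0.4)),
                             h2_target = 0.59, trait_name = "hyp",
                             mean = 387, sd = 141, seed = 2)
heritability(pheno, "hyp")

grid <- dosage_grid(geno, step_cM = 1)
y <- strain_values(summarize_strains(pheno), "hyp", "both")
scan <- scan_trait(y, grid, trait = "hyp")
thr <- permutation_thresholds(y, grid, n_perm = 1000, seed = 3)
detect_pqtls(scan, thr)
plot(scan, thresholds = thr)
```
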