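---
title: "Gatekeeper cross-trait testing and colocalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gatekeeper cross-trait testing and colocalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

This vignette is the package's own account of the statistics it implements:
the gatekeeper test and its error-rate guarantee, the colocalization model,
the harmonization and resource-handling conventions, what the synthetic
generator does and does not emulate, and the design decisions taken where the
procedure was genuinely open.

## The gatekeeper test

Given two traits A and B with genome-wide significant lead variants and full
summary statistics, we ask: which of A's leads are also associated with B
(and vice versa)? Testing every genomic variant against B would require
genome-wide multiplicity correction; instead, the candidate set is restricted
to the pooled lead variants of the pair. With $m$ testable pooled variants,
each cross-trait lookup is declared significant when the other trait's
p-value satisfies $p < \alpha/m$ (strict inequality, full precision), with
$\alpha = 0.05$.

This controls the family-wise error rate for joint association: conditional
on the first-stage selection, the second-stage p-values are ordinary
association p-values in an independent dataset, so under the global null

$$\Pr(\text{any declaration}) = 1 - (1 - \alpha/m)^m < \alpha
\quad (m > 1; = \alpha \text{ at } m = 1).$$

`simulate_null_fwer()` verifies this empirically; at $m = 172$ the analytic
value is $\approx 0.0488$.

Practical details that matter:

* **MHC/HLA exclusion.** Lead variants inside the major histocompatibility
  complex are removed before pooling (`exclude_region()`, default
  chr6:25–35 Mb on hg38, configurable). The region's megabase-scale LD makes
  a "shared locus" call there uninterpretable.
* **Pooling.** A variant that is a lead for both traits enters the pool once
  (`lead_for = "both"`), is tested in both lookup directions, but
  contributes 1 to $m$. The alternative ("count twice") was considered and
  rejected: $m$ counts tested *variants*, and the lookup p-values for the
  two directions concern the same variant.
* **Proxy rescue.** A pooled lead absent from the other trait's data is
  replaced by its best available LD proxy with $r^2$ strictly greater than
  0.8 (`best_proxy()`). Ties on $r^2$ break by genomic distance to the
  query, then lexicographically smallest id, making the lookup independent
  of proxy-table row order. No distance cap is applied to the proxy search.
* **Effect directions.** Each hit is labelled concordant/discordant from the
  signs of the two harmonized betas; a zero beta gives "indeterminate".
  Reports carry `OR = exp(beta)` alongside each beta.

## Harmonization

`harmonize_pair()` intersects two tables on variant identity — shared rsID
first, then `chrom:pos` for ids private to one table — and expresses both
traits on the first table's effect allele. A swapped coding (`a1`/`a2`
exchanged) flips the second trait's beta sign; any other allele disagreement
drops the variant ("allele mismatch"). Strand-ambiguous SNVs (A/T, C/G),
whose strand cannot be resolved from allele codes, are removed. Indels
harmonize by exact string match or swap only; no left-alignment or
normalization is attempted. Multi-allelic sites are treated as distinct
records per allele pair. Duplicate ids within one table keep the
smallest-p record.

One consequence worth knowing: because harmonization precedes the
gatekeeper stage, strand-ambiguous lead variants are not cross-testable
here, which is slightly more conservative than looking them up in
unharmonized statistics and resolving ambiguity afterwards.

p-values are stored on the natural scale; values below
`min_representable_p()` (the smallest positive normalized double,
$\approx 2.2\times10^{-308}$) are clamped to it, and all threshold
comparisons are strict.

Two effective-sample-size formulas for case–control GWAS are provided:
per-variant, $N_{eff} = (4/(2\,\mathrm{MAF}(1-\mathrm{MAF})\,\mathrm{INFO})
- \beta^2)/SE^2$ with missing INFO treated as 1 and negative results
reported as missing (never negative); and study-wide,
$N_{eff} = 4/(1/N_{cas} + 1/N_{con})$.

## Colocalization

At each significant hit, the locus is all harmonized variants in the same
approximately independent LD block as the tested variant (blocks loaded from
BED3, half-open 0-based intervals; a 1-based position $p$ belongs to the
block containing $p-1$). Each trait's per-variant evidence is a Wakefield
approximate Bayes factor

$$\log \mathrm{ABF} = \tfrac12\log(1 - r) + \tfrac12 z^2 r,
\qquad r = \frac{W}{V + W},\; V = se^2,\; z = \beta/se,$$

with prior effect scale $\sqrt W$ = `prior_sd` (default 0.2 per trait on the
log-odds scale, the conventional case–control value). Five hypotheses are
compared — H0 no causal variant, H1/H2 one trait only, H3 two distinct
causal variants, H4 one shared causal variant — with per-variant priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (all four config-exposed).
`pp_shared` is PP(H4) and `pp_distinct` is PP(H3).

Numerical choices: all accumulation is in log space with log-sum-exp; H3's
difference of exponentials uses $\log(e^a - e^b) = a + \log(1 - e^{b-a})$
for $a \ge b$, and degenerates to exactly $-\infty$ (posterior 0) when the
difference is non-positive — in particular at $n = 1$, where no
distinct-variant configuration exists. A zero $p_{12}$ zeroes H4 exactly
rather than erroring. Variants without usable (beta, se) in both traits are
dropped from the locus with a count. The test suite checks the log-space
implementation against a brute-force enumeration of all $1 + 2n + n^2$
causal configurations to $10^{-9}$.

The model assumes at most one causal variant per trait per locus. Loci with
multiple independent signals violate this; extensions conditioning on an LD
matrix exist but are out of scope (they need an LD reference matched to the
GWAS cohort). When two significant leads fall in the same block, the block
is colocalized once and both report rows carry the same posterior and block
id.

## The synthetic generator

`simulate_locus_pair()` emulates the statistical structure the analysis
assumes, directly at the summary level. For a locus of $n$ variants with
AR(1) LD matrix $R_{ij} = \rho^{|i-j|}$:

* MAFs are uniform on [0.05, 0.5] (common-variant GWAS panels); per-variant
  standard errors are $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,N_{eff}}$
  with $N_{eff}$ from the case/control counts.
* The causal configuration (shared / distinct / one-trait / null) places a
  standardized effect $\lambda_c = \beta_c / se_c$ at the causal index;
  z-scores are drawn from $\mathcal N(R\lambda,\, R)$, so causal signal
  leaks into LD neighbours exactly as in real marginal statistics, and
  $\beta_i = z_i \, se_i$.
* Lead lists are each trait's per-locus minimum-p variant among those with
  $p < 5\times10^{-8}$; the proxy table is derived from the same LD
  ($r^2 = \rho^{2|i-j|}$, written above 0.5); each locus occupies its own
  1-Mb block.

Reference conditions (the defaults, chosen once): per-trait case/control
counts 21,982/41,944 — a realistic published case–control GWAS scale giving
$N_{eff} \approx 57{,}693$ — causal log-odds effects of 0.05 (OR ≈ 1.05,
comfortably genome-wide significant at that $N_{eff}$), $\rho = 0.9$, and
default causal placement at $n/2$ (shared) or $n/4$ and $3n/4$ (distinct;
$r^2 \approx \rho^n$ between the two, i.e. weak LD). A `causal_z` option
sets $\beta_c = z\,se_c$ instead, pinning the expected causal z-score. A
configurable fraction of trait 2's records is re-encoded on the opposite
allele with negated beta (exercising harmonization), and an optional
fraction of strand-ambiguous allele codes is available (default 0).

What the generator does **not** emulate — so what passing tests do not show
about real data: realistic haplotype block structure (AR(1) is a deliberate
simplification), sample overlap between the two traits (shared controls
induce correlated errors and inflate apparent pleiotropy; an extension hook,
not implemented), genotyping/imputation artefacts, population stratification,
and multi-signal loci.

Simulation scales used by the test suite (chosen as a balance of precision
and turnaround): 2,000 replicates for the null-FWER check, 200 loci per
causal configuration at causal $z \approx 6$ and $n = 25$ for posterior
recovery, 10,000 variants for null p-value calibration. At these settings
the whole suite runs in well under five minutes. One recovery property is
knowingly strict: at causal $z \approx 6$, roughly 12% of loci per trait
realize a causal z below the H3-versus-H1/H2 posterior boundary (~4.8 under
the default priors), so distinct-causal recovery by maximum posterior sits
near 76–79%, not above 80%; shared-causal recovery is ~99%. This is the
model's true behaviour at that signal strength (the implementation matches
exhaustive enumeration), not a numerical artefact.

## Pipeline behaviour and edge cases

`run_pair_analysis()` executes harmonize → exclude → pool → resolve →
threshold → cross-test → per-hit colocalize, and writes a report TSV plus a
run log (m, threshold, proxy substitutions, drop censuses, priors) from
which a methods paragraph can be reconstructed. Two degenerate outcomes are
distinguished deliberately: an empty pooled set (no genome-wide significant
leads anywhere) is a successful run with an empty report, whereas a
non-empty pool with zero testable variants is refused with a diagnostic —
the latter almost always indicates mismatched variant id conventions
between the two datasets.

The optional sensitivity join annotates each reported hit with a third
trait's OR and p-value and a nominal-significance flag ($p < 0.05$),
harmonized to the report's effect alleles; hits missing from the sensitivity
data are flagged, not dropped. Nearest-gene annotation is purely
interval-based (ties reported joined by `/`) and intentionally modest: the
nearest gene is a prior, not an identification of the causal gene.

## Known limitations

* Single-causal-variant colocalization; no credible sets or fine-mapping.
* No coordinate lift-over, no allele-frequency checks against a reference
  panel, no imputation.
* Genetic-correlation estimation (LD-score-style methods) is out of scope;
  only the SE back-calculation utilities used for reporting such estimates
  are included (`se_from_estimate_and_p()`, `ci95()`, which uses 1.96 by
  printed-table convention rather than the exact quantile).
* Shared-control inflation of cross-trait hits is not modelled or corrected.
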