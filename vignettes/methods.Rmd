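---
title: "Models and methods behind seqgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seqgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqgwas)
```

`seqgwas` studies one methodological question: when sequence genotypes
are imputed with modest accuracy, what does a single-SNP mixed-model
GWAS gain from carrying the imputation uncertainty in dosage scores
rather than filtering hard calls on accuracy? Because the commercial
pig data that motivate the question are proprietary, the package pairs
the analysis pipeline with a synthetic-data generator whose ground
truth is known, and every claim the package makes is a claim about that
generator. This vignette records the models, the parameters that
matter, and the design decisions that were genuinely open.

## The association model

For each SNP the pipeline fits

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{x} b + \mathbf{u} + \mathbf{e},
\qquad \mathbf{u} \sim N(\mathbf{0}, \mathbf{G}\sigma_g^2),
\qquad \mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma_e^2),$$

where $\mathbf{x}$ holds genotype scores (0/1/2) or dosage scores
(real-valued in $[0,2]$) — the two enter the identical code path. The
genomic relationship matrix is the Yang estimator in both printed
branches: off-diagonal entries average
$(x_{ij}-2p_i)(x_{ik}-2p_i)/\bigl(2p_i(1-p_i)\bigr)$ over SNPs, and the
diagonal is
$1 + \tfrac1N\sum_i \bigl(x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2\bigr)/\bigl(2p_i(1-p_i)\bigr)$.
$p_i$ is the counted-allele frequency; relabelling ref/alt and
replacing $p$ by $1-p$ leaves both branches unchanged (tested), so
whether one calls it "MAF" or "allele frequency" is immaterial. Missing
calls are mean-imputed to $2p_i$, the standard convention, and the same
imputation is used at tested SNPs. For dosage data the same formulas
apply with $x$ the dosage and $p$ half the mean dosage.

To avoid fitting a SNP against a relationship matrix that contains it,
all testing is leave-one-chromosome-out (LOCO): the GRM for chromosome
$c$ is built from every other chromosome's SNPs. `loco_grms()`
accumulates per-chromosome cross-product contributions once and
subtracts, so all $C$ matrices cost one full GRM; the result is
numerically identical to rebuilding each subset directly (tested to
1e-10).

Variance components are estimated once per chromosome by REML
(`reml_fit()`) and reused for every SNP on it. The GRM is
eigendecomposed, the restricted likelihood is profiled to a
one-dimensional search over $\delta = \sigma_g^2/\sigma_e^2$, and a
bounded Brent search on $\log\delta$ (argument tolerance 1e-9, with an
explicit comparison against the $\delta = 0$ boundary at likelihood
tolerance 1e-8) makes the fit deterministic. Two numerical edge cases
are handled explicitly:

- *Indefinite GRMs.* The Yang diagonal makes $\mathbf{G}$ slightly
  indefinite for rare-allele-heavy SNP sets (smallest eigenvalues a few
  percent of the largest). Eigenvalues are kept as-is and the $\delta$
  search is bounded so $\delta d_i + 1 > 0$, keeping $\mathbf{V}$
  positive definite; matrices with smallest eigenvalue below
  $-0.25\,\lambda_{\max}$ are rejected.
- *Identity GRMs.* When $\mathbf{G} \approx \mathbf{I}$ the two
  components are exchangeable; the fit is flagged
  `identifiable = FALSE` with the whole variance assigned to the
  residual instead of an arbitrary split.

Given the components, each SNP is tested by generalized least squares
of $\mathbf{y}$ on $[\mathbf{1}, \mathbf{x}]$ with $\mathbf{V}$ fixed;
$\hat b$, its standard error, the Wald $\chi^2 = (\hat b/se)^2$ and the
two-sided p-value follow in closed form in the rotated basis (one $O(n)$
scan per SNP after an $O(n^2)$ rotation). The GLS solution matches a
dense-matrix-inverse oracle to 1e-8 in the tests. With $\sigma_g^2 = 0$
it reduces exactly to OLS.

The percentage of phenotypic variance explained by a SNP is
$2p(1-p)\hat b^2/\mathrm{var}(y) \times 100$; the pipeline uses the
configured phenotypic variance (1.08 for line A, 0.96 for line B) as
the denominator.

## Significance machinery

P-values are converted to 1-df $\chi^2$ statistics, the genomic
inflation factor is $\lambda = \mathrm{median}(\chi^2)/0.4549364$, and
each track's statistics are divided by its own $\lambda$ before
thresholding (genomic control). The significance threshold is
$-\log_{10}(\alpha/M_e)$ with $\alpha = 0.05$ and $M_e$ the effective
number of independent chromosome segments, estimated as the reciprocal
variance of the off-diagonal GRM entries. For $K$ independent
standardized loci that variance is $\approx 1/K$, so $M_e$ recovers the
number of independent segments, and duplicating SNP columns (pure LD
redundancy) provably leaves it unchanged. Thresholding uses the
unrounded value; the one-decimal rounding (e.g. 4.2 from
$M_e = 782.3$, 3.7 from $M_e = 280.6$) is reporting convention only.
Within a pipeline run the default is one shared threshold from the
largest per-track $M_e$ (`shared_threshold = "max-me"`), matching the
practice of using one threshold per line when the per-density $M_e$
values are similar; `"per-track"` is available.

QTL regions are called greedily per chromosome: the most significant
unassigned SNP above threshold becomes a lead, every unassigned
significant SNP within ±0.5 Mb joins its region, repeat. Ties in
$-\log_{10}p$ — which dosage tracks genuinely produce in high-LD
regions — break deterministically on smaller chromosome, then smaller
position. The caller is tested identical to a brute-force re-scan
implementation on 100 randomized tables including ties. Region spans
are reported as the member extent (the lead ± window clipped to
members); membership, not span, is the defined quantity.

## The synthetic-data generator

**LD model.** Haplotypes follow a first-order Markov copying process
along each chromosome, applied to a latent uniform: the latent value is
copied from the previous SNP with probability
$c(d) = \exp\bigl(-d\,\ln(1/0.3)/(2\,\texttt{ld\_decay\_bp})\bigr)$ and
redrawn otherwise, and the allele is the indicator that the latent
value falls below the SNP's frequency. Copying the *quantile* rather
than the allele value was a deliberate choice: copying allele values
makes every marginal frequency converge to the chromosome average,
destroying the configured MAF spectrum (and with it the genotype-class
filter and the MAF-dependent accuracy curve). The latent form preserves
marginals exactly while giving equal-frequency SNP pairs correlation
$c(d)$, so $r^2$ at `ld_decay_bp` (default 0.5 Mb) is 0.3 for
equal-frequency pairs and smaller otherwise — the mean $r^2$ beyond
0.5 Mb stays below 0.3, the premise behind the ±0.5-Mb region window.
It remains a copying model, not a coalescent: no recombination maps,
no demography, no selection.

**MAF spectrum.** Default: 10 % of SNPs rare (uniform on
\[0.002, 0.01\]) and the rest log-uniform on \[0.01, 0.5\],
approximating a 1/p spectrum. Two lines are generated from separate
haplotype pools sharing one variant map with independently drawn
spectra, so SNPs have line-specific frequencies (a variant can be
common in one line and nearly absent in the other).

**Trait.** $y = \sum_c x_c b_c + e$ with causal SNPs sampled from a
candidate set. Two effect models are provided. The default,
`"standardized"`, draws $b_c = z_c/\sqrt{2p_c(1-p_c)}$ — each causal
SNP explains the same expected variance, which is precisely the
architecture the standardized GRM assumes, so REML heritability is an
estimand the generator actually realizes. `"iid"` draws $b_c$ directly
(rare variants then contribute little variance), appropriate when
emulating common-variant architectures. After orthogonalizing the
residual against the genetic value, both parts are rescaled so the
realized variance ratio is exactly `h2` and $\mathrm{var}(y)$ exactly
`pheno_var` — the generator realizes its targets rather than
approximating them.

**Imputation error.** For SNP $s$ with target accuracy $r^2_s$, set
$\pi_s = \sqrt{r^2_s}$. Each individual's observed genotype is the true
genotype with probability $\pi_s$, otherwise a fresh Hardy–Weinberg
draw at the SNP's frequency; the reported genotype-probability triplet
is $\pi_s\,\mathrm{onehot}(g_{obs}) + (1-\pi_s)\,\mathrm{HWE}(p_s)$,
the dosage its expectation, the hard call its argmax (first maximum on
ties, i.e. the lower genotype class). Since
$\mathrm{cov}(D, g) = \pi_s^2\,\mathrm{var}(g)$ and
$\mathrm{var}(D) = \pi_s^2\,\mathrm{var}(g)$, the squared correlation
with the truth is $\pi_s^2 = r^2_s$ in expectation — the mechanism is
analytically calibrated, unlike additive-noise-plus-clipping schemes,
and the acceptance script verifies per-MAF-bin calibration at n = 2000.
The GP tracks are built from the *resampled* genotype, never the truth,
so exported posterior tracks do not leak ground truth. The target curve
is $r^2(\mathrm{maf}) = \mathrm{plateau}\,(1 - e^{-\mathrm{maf}/\mathrm{scale}})$
with plateaus 0.9 (line A) and 0.7 (line B) and scale 0.05, i.e. most
of the rise happens below MAF 0.15; the saturating-exponential form is
a modelling choice — only the rise-then-plateau shape is prescribed by
the data being emulated.

**Sequencing annotations.** Depth is Poisson with mean 11.6; site QUAL
is a shifted gamma (defaults put roughly 9 % of sites below Phred 20);
missingness is independent Bernoulli (default 3 %). Only the filter
thresholds downstream matter, so no attempt is made at realistic error
profiles, reference bias, or read-level simulation.

**Key defaults and why.** `h2 = 0.4` (the trait emulated is highly
heritable), `pheno_var` 1.08 / 0.96 and `accuracy_plateau` 0.9 / 0.7
(line presets), `mean_depth = 11.6`, `n_individuals = 1000` and
`n_snps_sequence = 20000` over 10 chromosomes of 10 Mb (a desk-scale
genome that keeps LD decay meaningful at 0.5 Mb), `chip_fraction =
0.05` and `dense_fraction = 0.25` (desk-scale analogues preserving the
sparse < dense < sequence ordering), `n_causal = 50`.

## Quality control

Filters run in a documented order — indel, map, per-call depth masking
(outside 4–35 becomes missing), site QUAL (strictly above 20),
missingness (more than 20 % after masking), MAF (below 0.01),
genotype-class frequency (any class below 0.1), greedy keep-first 3-bp
spacing, accuracy ($R^2 \le 0.6$) — cheap and sequence-level before
expensive and panel-level. Each removed SNP is attributed to the first
rule that failed it, removal counts partition the input, and the
composition is idempotent. Boundary strictness follows the rules'
wording exactly: MAF < 0.01 out, QUAL ≤ 20 out, missing > 20 % out,
$R^2 \le 0.6$ out. Two type-driven deviations are deliberate: the
genotype-class filter is not applied to dosage tracks (no discrete
classes), and the accuracy filter is skipped for dosage tracks (the
scores carry the uncertainty). Both QC orderings for the imputed
hard-call track apply post-call; whether class frequencies should be
assessed pre- or post-imputation is unknowable from the emulated
design, and post-call is the only option available to a real pipeline.

The truth-free accuracy estimate is the allelic-$R^2$ form used by
posterior-probability imputation software:
$\widehat{\mathrm{Var}}(e)/(\bar u - \bar e^2)$ with
$e_i = GP_1 + 2GP_2$ and $u_i = GP_1 + 4GP_2$, clipped to $[0,1]$ and
0 on a vanishing denominator. Under the generator's mixture it
converges to $\pi^2$, the same limit as the truth-based squared
correlation, and the tests require the two to agree within 0.05 on
simulator output.

## Calibration experiments: design choices

Three choices in the acceptance experiments deserve explanation.

*QC before GRM.* REML with a single standardized GRM is biased under
MAF–LD stratification: with the rare-tilted sequence spectrum *and* LD,
heritability is systematically underestimated even when causal SNPs are
inside the GRM (this is the regime GREML-LDMS was invented for). The
emulated study never fits a GRM to raw sequence variants — its
genotype-class filter leaves only common SNPs — so the calibration
experiments likewise apply `genotype_qc()` before building GRMs and
drawing polygenic traits. In that regime REML recovery is unbiased, as
the acceptance script verifies.

*Effective tests for calibration intervals.* Tested SNPs are
LD-correlated by design, so comparing an empirical rejection rate
against a binomial interval at the raw SNP count would use an interval
with far less than 95 % coverage. The type-I-error check sizes its
interval by the effective number of independent tests — the package's
own $M_e$ of the tested SNP set. For the same reason a single run's
$\lambda$ (a median over ~10³ correlated $\chi^2$ values with only
~10² effective draws) has a standard deviation near 0.1, so the null
calibration reports the mean $\lambda$ over replicated genomes rather
than one noisy draw.

*Line B for the dosage comparison.* The dosage-vs-filtered-genotype
contrast is strongest where imputation is poor: in the low-accuracy
line (plateau 0.7) the accuracy filter discards many causal regions
outright, and the mass of attenuated low-MAF dosage SNPs dilutes the
median statistic, giving both more true-positive regions for the
dosage track and the lower inflation factor. In the high-accuracy line
the two tracks barely differ at desk scale and the $\lambda$ ordering
drowns in median noise. The comparison experiment therefore runs the
line-B conditions with i.i.d. allele-count effects (the common-variant
architecture under which accuracy/chip ascertainment operates);
standardized effects would hand the dosage track's retained rare SNPs
outsized effects and reverse the mechanism being studied.

## What passing tests do and do not show

The generator realizes LD decay, line divergence, a heritable trait and
calibrated imputation error, but real sequence data differ in ways the
package does not model: coalescent genealogies and recombination
hotspots, selection and pedigree structure within lines, systematic
(haplotype-correlated, MAF-asymmetric) imputation errors from a shared
reference panel, multi-allelic sites and indels, and genotyping error
on the chips. Directional results on the simulator — more QTL regions
and lower inflation with dosage scores — reproduce the *mechanisms*
claimed for the real data, not the real data's magnitudes; published
headline numbers (SNP counts, average accuracies, region counts,
inflation factors) depend on the proprietary data and are out of scope.
Desk-scale problem sizes (n ≤ 2000, ≤ 20k SNPs, 10–20 chromosomes) were
chosen so the full suite and the acceptance script each run in minutes;
all conclusions are statements about those sizes.
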