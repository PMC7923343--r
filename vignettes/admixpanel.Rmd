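---
title: "Methods: panel design, supervised admixture and opposing-homozygote parentage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel design, supervised admixture and opposing-homozygote parentage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`admixpanel` designs small SNP panels for two jobs in admixed dairy
cattle populations with a three-way ancestral structure — European
taurine dairy (EUT), African taurine (AFT) and indicine (BI): (i)
estimating each animal's total exotic dairy proportion, and (ii)
assigning parentage from opposing homozygotes. This vignette is the
package's account of the underlying models, the tunable parameters and
their defaults, the numerical choices, and what the bundled simulator
does and does not establish.

## 1. Supervised admixture model

For individual genotype dosages $g_j \in \{0,1,2\}$ (counts of allele A
at SNP $j$) and fixed reference allele frequencies $p_{kj}$ for $K$
reference populations, the ancestry vector $q$ on the simplex maximizes

$$\ell(q) = \sum_j \left[ g_j \ln \theta_j + (2-g_j)\ln(1-\theta_j)
\right], \qquad \theta_j = \sum_k q_k\, p_{kj},$$

i.e. each allele copy is an independent draw from a mixture of the
reference frequencies. Assumptions worth stating: loci are treated as
independent (no LD correction — which is precisely why panels are
pruned by physical distance), reference frequencies are known without
error (in practice they are estimates from finite reference samples,
which is the dominant noise source for small panels), and
Hardy–Weinberg proportions hold within ancestral components.

The maximizer is found by EM-style multiplicative updates
$$q_k \leftarrow \frac{q_k}{2M}\sum_j \left[
\frac{g_j\,p_{kj}}{\theta_j} + \frac{(2-g_j)(1-p_{kj})}{1-\theta_j}
\right],$$
with $M$ the number of called SNPs for that individual. Each update is
an exact EM step for the allele-origin latent variable, so the
log-likelihood is non-decreasing — the test-suite asserts this on
traces. Numerical choices:

* **Initialization** is uniform ($q_k = 1/K$), deterministic, so
  estimates are reproducible without seeds.
* **Convergence** is declared when the relative change of $\ell$ falls
  below `tol` (default `1e-7`), with a cap of `max_iter = 2000`.
* **Clamping**: reference frequencies are clamped to
  $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, so fixed or
  lost alleles cannot produce infinite log-likelihoods.
* **Unidentifiable inputs**: if the likelihood cannot improve at all
  from the uniform start (identical frequency rows for every reference
  make $\ell$ flat), the uniform initialization is returned with
  `converged = FALSE` rather than pretending an arbitrary interior
  point is an estimate. The flatness test is
  $\ell - \ell_0 \le |\ell_0|\cdot 10^{-12}$; an individual whose true
  optimum is exactly the uniform point would also be flagged, which we
  accept as the conservative direction.
* Missing genotypes are skipped (their terms are dropped from both the
  likelihood and the update); an all-missing individual keeps the
  uniform vector and `converged = FALSE`.

Total dairy proportion is $\sum_{k \in \mathrm{dairy}} q_k$. Panel
accuracy is the squared Pearson correlation $r^2$ between panel
estimates and a baseline, computed by the explicit sum formula; the
baseline in experiments is the full-marker estimate (truth is also
reported when the data are simulated, since then it exists).

## 2. Panel selection and stepwise pruning

Selection scores are absolute allele-frequency differences
$|pA_i - pA_j|$ between ancestral populations — the simplest measure of
per-SNP ancestry information, symmetric in the populations and
invariant to which allele is counted. Three criteria are provided:

* **weighted pool**: score $|p_{EUT} - (w\,p_{AFT} + (1-w)\,p_{BI})|$
  against a hypothetical ancestral pool, $w \in (0,1)$ in practice on
  the grid $0.1,\dots,0.9$;
* **split fraction**: $\lceil f\,n\rceil$ SNPs of each size-$n$ panel
  from the AFT-vs-EUT ranking, the remainder from BI-vs-EUT;
* **MAF** (for parentage): rank by minor allele frequency in the
  crossbred target population, highest first.

Ties are broken deterministically by (chromosome, position, snp id);
SNPs with undefined frequencies in a required population are excluded
from ranking rather than imputed.

**Pruning** controls clustering of selected SNPs (clusters carry
redundant, LD-shared information and were observed to depress
accuracy). It is population-independent — a greedy scan of the ranked
list where a candidate is accepted only if it lies at least a minimum
physical distance from every already-accepted SNP on the same
chromosome. The distance relaxes as the panel grows: the default
breed-proportion schedule requires 3.5 Mb for the first 100 accepted
SNPs, 3.0 Mb up to 300, and 1.25 Mb thereafter; the parentage schedule
is a flat 1 Mb. The stage is a function of the *total* count accepted
so far, not per chromosome. Cross-chromosome distances are infinite by
convention. An independent checker (`check_panel_distances`, a full
pairwise scan) re-validates every emitted panel in the test-suite.

Two design points were genuinely open and are fixed as follows:

* **Split-mode construction.** Combining two independently pruned
  rankings can violate distances jointly. The implementation therefore
  builds the combined panel in one greedy pass — drawing from the
  AFT-vs-EUT ranking until the $\lceil f\,n\rceil$ quota, then from
  BI-vs-EUT, checking every candidate against the combined panel so
  far. A SNP ranked in both lists enters once, attributed to the list
  that consumed it first; the other list supplies its next eligible
  SNP. This guarantees quota, deduplication, schedule compliance and
  exact nesting simultaneously.
* **Rounding** of the split quota uses the ceiling, fixed and
  documented.

Panels are **nested by construction**: the order in which SNPs are
accepted is the panel order, so any prefix is a valid smaller panel.
Nesting is asserted exactly in the tests. When the universe cannot
supply the largest requested size under the schedule, the panel is
emitted at its achieved size with a shortfall warning.

## 3. Parentage assignment

For two individuals, `opH` counts SNPs where one is homozygous 0 and
the other homozygous 2, over SNPs called in both. A pair is assigned
when `opH` is *strictly* less than 1% of the number of markers in the
assay — the assay size, not the per-pair comparable count, is the
denominator, so missingness makes assignment conservative rather than
lenient. Strictness at the boundary is a fixed decision.

Search scenarios: (1) all unordered pairs among $N$ genotyped animals,
$N(N-1)/2$ of them; (2) known parents × progeny only. Panel quality is
summarized by the separation value
$sv = \min(\mathrm{opH}\ \mathrm{over\ false\ pairs}) -
\max(\mathrm{opH}\ \mathrm{over\ true\ pairs})$ — positive $sv$ means a
clean threshold exists — and by $Pa$ (correct assignments / parents)
and $Pe$ (1 − incorrect assignments / parents). Because scenario 2's
false-pair set is a subset of scenario 1's while the true pairs are
identical, scenario-2 $sv$ can never be smaller — asserted on every
simulated seed. A progeny matching several candidates under the
threshold keeps all passing pairs (no disambiguation rule is imposed);
$Pe$ is clamped to $[0,1]$ since the raw formula can go negative when
false assignments exceed the parent count.

## 4. The synthetic world

The simulator exists so that selection, estimation and parentage are
exercised end-to-end without restricted genotype data. Its defaults
*are* the stated world of the test-suite and were frozen before the
acceptance measurements:

| Parameter | Default | Why |
|---|---|---|
| chromosomes | 29 autosomes, ~2.5 Gb | cattle-like genome so the Mb-scale schedules bind realistically |
| ancestral law for $p_0$ | Uniform(0.05, 0.95) | broad spectrum; no attempt to copy array ascertainment |
| divergence $F$ (EUT, AFT, BI) | 0.205, 0.335, 0.525 | Balding–Nichols: $p_k \sim \mathrm{Beta}(p_0\frac{1-F}{F},(1-p_0)\frac{1-F}{F})$; pairwise differentiation of two such populations is $\approx (F_i+F_j)/2$, solved once against the midpoints of the observed ranges AFT–EUT 0.211–0.332, EUT–BI 0.301–0.427, AFT–BI 0.372–0.492; realized values ≈ 0.27/0.36/0.43 |
| admixture law | dairy ∼ Beta(3.5, 2.1); AFT share of remainder ∼ Beta(2, 3) | mean dairy fraction 0.625, s.d. ≈ 0.19, matching reported crossbred means near 0.5–0.7; indigenous remainder leans indicine |
| reference samples | 40 per ancestral group | same order as real reference breed panels (≈ 14–105) |
| crossbreds / families | 500 / 25 | enough individuals for stable $r^2$; family count ≈ 10% of the population, echoing observed parent fractions |
| error rate | 0.01 per genotype | uniform substitution among the other two dosages — documented so analytic expectations (below) are well-defined |

Crossbred genotypes are drawn as $\mathrm{Binomial}(2, \theta_j)$ with
$\theta_j = \sum_k q_k p_{kj}$ — i.e. the *estimator's own* sampling
model. Offspring receive one allele transmitted from a genotyped
parent and one from an ungenotyped mate drawn from population
frequencies, so a true pair has zero opposing homozygotes before error
injection.

**What a green test establishes — and what it does not.** The
generator matches the estimator's likelihood exactly (no LD, no
inbreeding, no ascertainment bias, reference breeds are the actual
mixture components). Parameter-recovery results on it are therefore a
*correctness* check of the machinery and a *ceiling* for real-data
performance, not a forecast of it. In particular the real allele
frequency spectra of array data are strongly ascertainment-biased;
the uniform $p_0$ law makes no attempt to copy that, and accuracies on
real arrays will differ. Linkage, selection, and deeper pedigrees are
out of scope.

**The opposing-homozygote error budget.** Under the uniform
substitution model, a true pair becomes opposing at a called SNP with
probability $c(p)\,e$ per unit error rate $e$, where
$c(p) = p^3 + q^3 + pq$ (homozygote–homozygote pairs, weight
$p^3+q^3$, flip with probability $e$; homozygote–heterozygote pairs,
weight $2pq$, flip opposite with probability $e/2$): $c = 0.5$ at
MAF 0.5 and ≈ 0.66 averaged over the simulated spectrum. At the
default $e = 0.01$ the expected true-pair inconsistency fraction is
≈ 0.5–0.66% of markers — uncomfortably close to the 1% assignment
budget. Two consequences are deliberately left as failing acceptance
assertions rather than papered over: at 300 SNPs the strict budget is
3 opposing homozygotes while true pairs average 1.5, so with 25
families some pair nearly always exceeds it ($Pa = 1$ is essentially
unreachable); and at 5000 SNPs the budget (50) sits only ≈ 2.7 s.d.
above the true-pair mean (≈ 33), so exact full-set pedigree recovery
fails on rare seeds even though the separation value is hugely
positive (closest false pair ≈ 260). With realistic array error rates
(0.1–0.5%) both assertions would pass comfortably; the 1% *error rate*
of the stated world conflates the assignment *allowance* with the
error process it insures against. We kept the stated world and the
honest red rather than tuning either.

## 5. Known limitations

* The PLINK text dialect carries no allele-order metadata; on read the
  counted allele defaults to the alphabetically smaller one, with an
  `alleles =` override for exact round-trips of arbitrary codings.
* Pooled reference groups are formed by pooling individuals; an
  unweighted breed-mean alternative (`breed_mean_frequency`) exists
  for sensitivity checks only.
* The estimator is supervised only: reference frequencies are never
  updated, and no cross-validation over $K$ is offered.
* Greedy ranking plus pruning is not an optimal-subset search; it is
  the field-standard, auditable procedure.
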