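---
title: "Modelling reproductive efficiency across parities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reproductive efficiency across parities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The trait and the problem

Reproductive efficiency (Re) is an indirect fertility measure for beef cows
kept in extensive systems, where direct fertility recording is impractical.
A cow on the optimal schedule calves first at `afc_opt = 24` months and
every `ci_opt = 12` months thereafter. For the n-th calving at age $t_n$
(months), the package's default time-ratio form is

$$Re_n = 100\,\frac{24 + 12\,(n-1)}{t_n},$$

the percentage of optimal reproductive progress actually realized, capped
at 100 by default (cows ahead of schedule are "on time", not better than
optimal). The original definition of the trait is verbal — the deviation
between optimal and realized parity number at each age — and admits a
second reading as a count ratio (realized over optimal parity count at age
$t_n$). Both are implemented behind `compute_re(formula = )`; the time
ratio is the default because it is continuous in age, reproduces the
documented range of the trait (minimum about 33 when a first calving
happens around six years of age), and changes smoothly across parities.
Neither form is asserted to be the original author's exact formula, which
is why the switch is exposed and auditable.

The cap is a censoring operation: it truncates the upper tail at 100. All
parameter-recovery validation therefore simulates and fits on the
*uncapped* scale, where the linear mixed model is the exact generative
truth; the cap is applied when emulating field data tables.

## Pedigree machinery

Inbreeding coefficients use the Meuwissen–Luo algorithm: $a_{ii} = \sum_j
L_{ij}^2 d_j$ accumulated over each animal's ancestors, with
Mendelian-sampling variances $d_i = 0.5 - 0.25(F_s + F_d)$ (both parents
known), $0.75 - 0.25 F_{known}$ (one parent), 1 (founder). No dense
relationship matrix is ever formed for model fitting: `a_inverse_sparse()`
builds $A^{-1}$ directly from parent triplets by Henderson's rules with
inbreeding, and carries $\log|A| = \sum_i \log d_i$ as an attribute for the
REML likelihood. The dense tabular $A$ (`a_matrix_tabular()`) exists only
as a test oracle and refuses pedigrees beyond a size guard.

Unknown parents are treated as unrelated founders; genetic groups are out
of scope. Inbreeding enters the models as a fixed effect in classes of
width 0.02. The class count defaults to 15 (the top class absorbing
everything above) and is configurable — the source material is internally
inconsistent between 15 and 16 classes, so the count was deliberately left
as a knob rather than hard-coded.

## The two genetic models

Both are animal models fitted by REML on the analysis table (one row per
calving, parities 1–9).

**Repeatability model (Rep).** Fixed calving-number and inbreeding-class
effects; random animal ($A\sigma^2_a$), permanent environment, and
herd-year-season (HYS) effects; one residual class. Heritability is
$\sigma^2_a/\sigma^2_{tot}$ and repeatability
$(\sigma^2_a+\sigma^2_p)/\sigma^2_{tot}$.

**Random-regression model (RA).** The animal effect is an order-$r$
regression on normalized Legendre polynomials
$\phi_k(x)=\sqrt{(2k+1)/2}P_k(x)$ over the calving number standardized to
$[-1,1]$; the coefficient covariance $K_a$ gives the genetic covariance
$A \otimes K_a$. Fixed effects are order-$r$ Legendre regressions on the
calving number and on the inbreeding-class midpoint; permanent environment
and HYS stay scalar; the residual variance has six classes indexed by
$\min(Cn, 6)$. Parity-specific parameters come from the covariance
function: $\sigma^2_{a,i} = \Phi_i K_a \Phi_i'$, heritabilities
$h^2_i$, genetic correlations $r_{g,ij}$, and per-animal genetic
trajectories $EGV_{mi} = \Phi_i a_m'$. Variance-parameter counts are
$(r+1)(r+2)/2 + 2 + 6$: 11 for $r=1$, 14 for $r=2$.

The normalization of the Legendre basis is a convention, not a substantive
choice: it changes the numerical values inside $K_a$ but not
$\Phi K_a \Phi'$, heritabilities, correlations, or EGVs. Evaluation is
restricted to the nine integer calving classes; no extrapolation is
offered.

HYS is treated as random in both models, and the number of records is used
as $n$ in BIC.

## REML: the engineering decision

Each likelihood evaluation assembles the sparse mixed-model equations
$C(\theta)$ and uses the identity
$$-2\,l_R = \log|R| + \log|G| + \log|C| + y'Py + (n-p)\log 2\pi .$$
$y'Py$ falls out of one sparse Cholesky solve;
$\log|G|$ for the animal block uses $\log|A\otimes K_a| = k\log|A| +
q\log|K_a|$ with $\log|A|$ precomputed from the pedigree.

The optimizer is `nlminb` on an unconstrained scale: log variances, and
the log-Cholesky factor of $K_a$, which keeps every iterate positive
definite without penalties or step-halving. This quasi-Newton/sparse-MME
route was chosen over EM with average-information acceleration because (i)
EM updates need traces of blocks of $C^{-1}$, i.e. selected-inverse
machinery the sparse-matrix backend does not expose, while the profiled
deviance needs only factorize-and-solve; and (ii) the Cholesky
parameterization gives positive definiteness for free, where AI-REML needs
guarded updates. Convergence uses a relative-tolerance of $10^{-8}$ on the
objective with at most 200 iterations; variances are floored at $10^{-8}$
times the phenotypic variance, and parameters stopping at that floor are
reported as pinned with a warning. Designs that make a component
structurally unidentifiable (a single record per cow and the
permanent-environment variance) are detected up front and the component is
held at the floor. Starting values split the phenotypic variance 40/30/10/20
across animal/permanent/HYS/residual.

Two performance details matter for the package's practicality: the
coefficient-matrix sparsity pattern is fixed across iterations, so values
are assembled into a precomputed template via index maps and the symbolic
Cholesky factorization is computed once and reused; and the per-class
cross-products $W'W_c$, $W'y_c$ are computed once per fit.

Correctness of the engine is established two ways: on unrelated animals
the fit agrees with an independent general-purpose mixed-model
implementation (components and the REML criterion itself), and the
repeatability model is recovered exactly as the $r=0$, one-residual-class,
class-fixed-effects special case of the random-regression fit
(`fit_rrm(fixed_form = "classes")`).

## Composite index

The nine per-calving EGVs of each animal are column-standardized and
decomposed by PCA on their correlation matrix. Scores on the first two
components are summed into $IpcT = Ipc_1 + Ipc_2$; with a rank-3 genetic
covariance and strongly positively correlated parities, two components
carry nearly all the variance, the first eigenvector is close to uniform
(a "size" vector) and the second changes sign mid-trajectory (a "shape"
vector). Eigenvector signs are fixed deterministically by making the
largest-magnitude loading positive. The genotyping cohort is the union of
a top slice of the IpcT ranking and the most negative animals (defaults
212 and 40).

## Association scan

Genotype QC follows the stated rules verbatim: markers with call rate
$\le 0.95$ or MAF $< 0.05$ are excluded (both boundaries as written), then
greedy windowed LD pruning (50-marker windows, step 5, $r^2 > 0.5$
resolved by removing the later marker — the tie-break is fixed for
determinism because the reference tool's behaviour is version-dependent).
The scan model is the standard univariate LMM $y = W\alpha + x\beta + u +
\epsilon$ with $u \sim N(0, \lambda\tau^{-1}K)$, $K$ the centered genomic
relationship matrix built from pruned markers and $W$ an intercept plus
ten stratification PCs (computed on pruned markers). $K$ is
eigendecomposed once; $\lambda$ is estimated by 1-D REML on the rotated
data, and each marker is then tested by GLS at $\hat\lambda$ with a Wald
statistic referred to $F(1, n-c-1)$. Missing genotypes are mean-imputed
per marker after QC. The hit rule defaults to $p < 10^{-4}$ with a
genome-wide flag at $10^{-5}$ (both thresholds appear in the source
material; the text's rule is the default). Candidate genes are looked up
in a local annotation table over closed $\pm 500$ kb windows; no web
queries are made.

PLINK-1 binary files are read and written natively (2-bit SNP-major
codes), since the analysis stack standardizes on that interchange format.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: a multi-generation
pedigree with heavy sire reuse (nonzero inbreeding in later generations);
records over parities 1–9 with geometric dropout (retention 0.8 per
calving); a population mean of 72%; additive genetic structure from a
3-coefficient covariance `default_ka_true()`; permanent-environment
variance 25, HYS variance 12; and six residual classes (349.75, 117.38,
61.71, 39.72, 28.97, 8.87).

`default_ka_true()` was constructed once, before any fitting, by
projecting a target nine-parity genetic covariance — the published
declining variance trajectory (123.2 at parity 1 to 37.8 at parity 9)
with a high-positive correlation profile (no pair below about 0.66) —
onto the rank-3 Legendre structure and flooring the eigenvalues. Its
implied trajectory runs 120 → 42. The permanent and HYS magnitudes are
package choices (the source prints them only for the repeatability model,
where they are 105.55 and 27.38 and are used as the repeatability-model
simulation truth); they were set so that the class-wise residuals,
obtained by subtracting genetic, permanent and HYS variance from the
published total-variance trajectory, remain positive. The inbreeding
fixed effect is simulated as linear in F (default slope −15, mild
inbreeding depression); the Cn fixed-effect profile rises linearly from
−6 to +6, matching the observation that Re grows almost linearly with
calving number.

Genotypes are Hardy–Weinberg draws at frequencies uniform on
[0.05, 0.5], optionally from two Balding–Nichols subpopulations; the
pseudo-phenotype is a standardized causal score scaled to a chosen
heritability plus Gaussian noise. The generator does **not** produce
realistic linkage disequilibrium (no coalescent), selection-driven
matings, or culling correlated with the trait — so passing tests show the
estimators are correct under the assumed model, not that field data meet
those assumptions. Calving dates are derived from the generated Re values,
so the phenotype module can re-derive the table from raw records.

## Validation sizes and numerical choices

The validation suite runs at deliberately moderate sizes, chosen as the
package's own accuracy/runtime trade-off and stated here for
reproducibility: repeatability-model recovery uses 8 replicates of ~1,250
recorded cows, random-regression recovery 6 replicates of ~1,000 cows
(both checked against the generating truth within two Monte-Carlo
standard errors of the replicate mean); model-ranking checks use 8
replicates of ~700 cows; scan calibration pools 12 null scans of 252
samples x 3,000 markers (Kolmogorov–Smirnov uniformity and
genomic-control inflation within [0.9, 1.1]) and 20 power replicates with
one causal locus at 15% variance. Degenerate inputs are handled
explicitly rather than numerically: empty record tables, zero-variance
EGV columns, monomorphic markers, flat likelihood profiles
($K \propto I$), cows with out-of-order calving dates, and pedigree cycles
all raise targeted errors or warnings.

## Known limitations

Single-trait models only; no genomic-pedigree blending, genetic groups,
dominance, or standard errors of heritability by Taylor expansion
(bootstrap over replicates is the supported route). The random-regression
order is limited to $r \le 2$, the range the trajectory data support.
The association model is single-locus; no multi-locus or imputation
machinery is provided. Real genotype positions and gene annotations must
be supplied by the user as local tables.
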