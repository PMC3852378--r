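---
title: "Frequency increment tests with reference loci: models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency increment tests with reference loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitr)
```

## The statistical model

A diallelic locus is observed at times $t_0 = 0 < t_1 < \dots < t_L$
(generations), giving population frequencies $x_0, \dots, x_L$ of one
allele. Under the Wright–Fisher model with $N$ diploids and no selection,
the change over one generation is a binomial draw with $2N$ trials, so for
$\Delta t_i = t_i - t_{i-1}$ short relative to $N$ and $x_{i-1}$ away from
the boundaries, the standardized increment

$$Y_i = \frac{x_i - x_{i-1}}
             {\sqrt{2\,x_{i-1}(1 - x_{i-1})\,\Delta t_i}}$$

is approximately normal with mean zero, with one common variance across
intervals whenever $N$ is constant. The **FIT** (`fit_test()`) treats that
variance as an unknown nuisance and applies a one-sample $t$-test to
$Y_1,\dots,Y_L$: $t_\mathrm{FIT} = \bar Y / \sqrt{S^2/L}$ with the
unbiased variance $S^2$, referred to Student-$t$ with $L-1$ degrees of
freedom, two-sided. The $(L-1)$-denominator of $S^2$ is not a convention
here but a requirement: it is what makes the null exactly Student-$t$.

When $N(t)$ fluctuates, the $Y_i$ have interval-specific variances
$\propto 1/N_i$ ($N_i$ the variance effective size over the interval) and
the FIT's null breaks down — in practice it becomes conservative, severely
so under rapid growth or a deep bottleneck, which costs power.

The **FITR** (`fitr_test()`) calibrates each interval with $R$
independently evolving *neutral reference loci* that experience the same
demography. Writing
$\Delta x_{h,i} = (x_{h,i} - x_{h,i-1})/\sqrt{x_{h,i-1}(1-x_{h,i-1})}$
for locus $h$ (0 = focal), the per-interval statistic

$$t^{(i)} = \frac{\Delta x_{0,i}}
                 {\sqrt{\tfrac1R \sum_{h=1}^{R} \Delta x_{h,i}^2}}$$

is a standard-normal numerator over the square root of an independent
$\chi^2_R/R$, with $N_i$ and $\Delta t_i$ cancelling — hence exactly
Student-$t$ with $R$ degrees of freedom under neutrality of the focal
locus, *whatever* $N(t)$ does. The summary statistic is the standardized
sum $t_\mathrm{FITR} = L^{-1/2}\sum_i t^{(i)}$; the factor $L^{-1/2}$
makes it asymptotically standard normal in $R$ but is otherwise inert,
because the identical factor is applied to the null. The null is sampled
empirically (`fitr_null()`): $M$ draws of $L^{-1/2}\sum_{i=1}^L T_i$,
$T_i \sim t_R$ independent. For $L = 1$ the analytic $t_{R}$ p-value is
used instead.

Assumptions worth keeping in mind: references are neutral, diallelic,
unlinked to the focal locus and to each other (linkage equilibrium
suffices in practice — see the recombination experiments below);
increments are small relative to $N_i$; frequencies are census values or
large samples. Sampling noise makes both tests conservative; reference
loci under weak selection ($N s \lesssim 5$, or $s_h \le s_0/2$) cost
little.

## p-values and degenerate inputs

* Both tests are two-sided; under neutrality this is the only symmetric
  choice yielding the nominal level.
* FITR p-values use the add-one Monte-Carlo estimator
  $(1 + \#\{|T_\mathrm{null}| \ge |t|\})/(M+1)$, which never returns 0;
  with the default $M = 10^5$ the smallest attainable p-value is
  $10^{-5}$.
* Null samples are cached in memory per $(L, R, M, \mathrm{seed})$ — a
  replicate driver testing $10^5$ datasets at the same design draws the
  null once. The draw is made under its own seed (default 1) without
  disturbing the caller's RNG stream, so p-values are deterministic given
  the data. An earlier design persisted the cache to disk; in-memory
  caching was kept instead because the draw costs well under a second and
  on-disk state complicates reproducibility more than it saves.
* A **reference locus** whose frequency is 0 or 1 at *any* sampled time is
  removed before computing the statistic (all-or-nothing per locus,
  `filter_reference_loci()`); the surviving count $R_\mathrm{used}$ sets
  the degrees of freedom. Once an allele fixes, its later increments are
  identically zero and carry no drift information, and the removal rule
  must be symmetric in time to be well-defined for the experiment drivers.
  This removal is *biased*: conditioning on non-fixation shrinks the
  reference increments, which inflates the neutral rejection rate by a few
  percent when references start near the boundary and $L$ is small (the
  effect is quantified in the validation suite). Use references with
  moderate starting frequencies (≥ 10%) where possible.
* The **focal locus** only needs interior frequencies at
  $t_0,\dots,t_{L-1}$: fixation exactly at $t_L$ leaves its last increment
  defined, and such trajectories are precisely the strongest selection
  signals, so they must not be discarded. Fixation *before* $t_L$ raises a
  distinct `fitr_focal_degenerate` error; all-references-removed raises
  `fitr_no_reference`; an interval where every reference increment is
  exactly zero raises `fitr_zero_denominator`. The drivers count such
  replicates separately (`n_degenerate`) and exclude them from rejection
  denominators rather than guessing an imputation.

## Demographic models and the generation-indexing convention

`demographic_model()` supports constant, exponential
($N(t) = \mathrm{round}(N_0 (N_T/N_0)^{t/T})$, hitting both endpoints
exactly) and piecewise-constant sizes; `builtin_model()` provides the five
validation scenarios (constant $10^4$; exponential $10^4\!\to\!10^5$;
moderate bottleneck $5\times10^4/10^4$; exponential $10^4\!\to\!10^8$;
severe bottleneck $10^6/10^4$) plus small-population variants (constant
100; the severe bottleneck divided by 200). Bottleneck windows are the
half-open $[0.5T, 0.75T)$, evaluated directly on integer generations
against the real-valued boundaries, so $T = 10$ places generations
$\{5,6,7\}$ inside.

One convention matters more than it looks: **the draw advancing the
population from generation $t-1$ to $t$ uses $N(t-1)$**, i.e. the drift
variance accrued over $(t-1, t]$ is $1/(2N(t-1))$. Equivalently, a
bottleneck declared on $[a, b)$ contributes exactly $b-a$ generations of
reduced size to the sampled increments. Under the alternative (offspring
indexing, $N(t)$), a sampling time placed exactly at a bottleneck edge
silently moves one generation of high-variance drift across the interval
boundary; with a $10^6/10^4$ bottleneck a single such generation carries
as much variance as 50 ordinary ones and visibly distorts power at the
affected intervals. The interval-based convention is also the one under
which $N_i$, the size "from $t_{i-1}$ to $t_i$", composes exactly from
per-generation sizes. For constant-$N$ models the two conventions
coincide.

## Simulators

`step_binomial()` is exact Wright–Fisher reproduction: post-selection
frequency $x' = x(1 + \tfrac12 s(1+x))/(1 + sx)$ (genic selection;
genotype fitnesses $1, 1+s/2, 1+s$), then $k/(2N)$ with
$k \sim \mathrm{Bin}(2N, x')$. It is the reference implementation but
impractical at $N = 10^6$–$10^8$.

`step_pseudo()` is the pseudo-sampling approximation used for large
populations: a normal draw with the binomial's mean and variance, clipped
to $[0,1]$, except when the expected minor-allele count $2N\min(x',1-x')$
is at most 5, where a Poisson draw of the minor-allele count (capped at
$2N$) replaces it — the normal approximation is poor exactly there.
Values clipped to 0 or 1 are treated as absorbed; the probability mass
involved is negligible at the $N$ where the normal branch is active. The
threshold of 5 expected copies is the conventional binomial/Poisson
switch-over; the validation suite checks pseudo-vs-binomial moment
agreement at $N \le 500$ and rate agreement at the experiment level.

`simulate_linked()` is an individual-based check of the independence
assumption: $N(t)$ diploids carried as haplotype pairs over $R+1$ ordered
loci, initialized in linkage equilibrium, parents drawn proportional to
multiplicative fitness across loci, gametes formed with crossover
probability $r$ between adjacent loci ($r = 0.5$ = free recombination).
Selection composes multiplicatively across loci — the standard genic
choice; with one selected locus (the validation setting) no composition
question arises. It refuses $N > 10^5$ (memory/time guard); at the scales
it is meant for ($N \approx 100$) the experiments show rejection rates
insensitive to $r$ all the way to complete linkage, which is what licenses
the fast independent-loci simulator everywhere else. Here the offspring
census count at generation $t$ is literally $N(t)$; its validation cells
use constant $N$, where this coincides with the interval convention above.

`sample_individuals()` overlays observation noise: each frequency becomes
$k/(2n)$, $k \sim \mathrm{Bin}(2n, x)$, for $n$ sampled diploids,
independently per locus and time point ("$n$ individuals" means $n$
diploids, $2n$ gene copies; pass $2n$ as $n$ for a haploid reading).

## What the generator emulates — and what it does not

The synthetic data are idealized: no mutation, no dominance, no
frequency-dependent or fluctuating selection, references exactly neutral
and exactly independent, census-accurate frequencies unless sampling noise
is explicitly added, and demography known only through its effect on
drift. Passing validation therefore shows that the *statistics* behave as
designed under their stated assumptions — it does not show robustness to
mis-specified references (linked to the target of selection, or
themselves selected beyond the weak regime), to pool-seq read noise, or to
time scales long enough for mutation to matter. The low-frequency
reference experiments deliberately violate one assumption (references near
the boundary) to quantify the resulting inflation.

## Validation scale

The validation suite estimates each operating characteristic from $10^4$
simulated replicates per grid cell (binomial standard error ≈ 0.22
percentage points near a 5% rate, ≈ 0.5 near 50%), with $10^5$ empirical
null draws per $(L, R)$ design; the acceptance script uses $10^5$
replicates for the pseudo-sampling cells and $10^4$ for the exact-binomial
and longest cells. These sizes were chosen as the package's validation
scale: rates are quoted with their Monte-Carlo standard errors, and any
comparison should use them. Per-cell seeds are derived from a master seed
by stable hashing of the cell coordinates, so any single cell of
`run_table()` reproduces independently of which subset is run.

## Known limitations

* Power at very small constant $N$ (say $N \approx 100$ with
  $T \le 20$) is intrinsically modest: the per-interval noncentrality is
  $\propto s\sqrt{2N\,\Delta t}$, and no choice of statistic recovers what
  drift has erased.
* The FITR needs $R_\mathrm{used} \ge 1$; with few, low-frequency
  references whole replicates become untestable, and the removal rule's
  inflation (above) applies.
* No estimation of $s$ is attempted — the tests detect departure from
  neutrality; effect-size estimation is a different problem.
* Multiple-testing across many focal loci is out of scope; combine the
  returned p-values with `p.adjust()` as appropriate.
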