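# fitr

Detecting natural selection from time-series allele-frequency data, with
population-size fluctuations handled through independent reference loci.

## The problem

Experimental evolution, ancient DNA and pool-seq time courses yield the
frequency of an allele at a diallelic locus at several time points
`t_0 = 0 < t_1 < … < t_L`. Under neutral Wright–Fisher drift the
standardized frequency increment over interval *i*,

    Y_i = (x_i − x_{i−1}) / sqrt(2 x_{i−1}(1 − x_{i−1})(t_i − t_{i−1})),

is approximately normal with mean 0 and a variance set by the (unknown)
population size, so the one-sample statistic

    t_FIT = Ȳ / sqrt(S² / L)

follows a Student-*t* distribution with L − 1 degrees of freedom — the
**frequency increment test (FIT)**. When the population size *fluctuates*,
the Y_i no longer share one variance and the FIT becomes conservative,
losing power precisely in the demographic scenarios (rapid growth, severe
bottlenecks) where selection scans are most interesting.

The **FITR** fixes this with R independently evolving *neutral reference
loci*, which experience the same demography. With
`Δx_{h,i} = (x_{h,i} − x_{h,i−1}) / sqrt(x_{h,i−1}(1 − x_{h,i−1}))`
(locus 0 focal, loci 1…R references),

    t^(i)  = Δx_{0,i} / sqrt( (1/R) Σ_h Δx_{h,i}² )        ~  t_R under H0
    t_FITR = (1/√L) Σ_i t^(i)

The per-interval effective population size and interval length cancel
between numerator and denominator, so t^(i) is exactly Student-*t* with R
degrees of freedom *irrespective of how N(t) fluctuates*; the null of
t_FITR is obtained empirically by summing L such *t* variables. The
package implements both tests, the reference-locus filtering rule (loci
fixed at a sampled time are removed), Wright–Fisher forward simulators
(exact binomial, fast pseudo-sampling, and an individual-based linked-loci
scheme with recombination), the demographic models used to validate the
tests, and replicate-level drivers for type-I error and power estimation.

## Worked example

Simulate a severe-bottleneck scenario (N = 10⁶ crashing to 10⁴ during
`[0.5T, 0.75T)`) with weak selection `s0 = 0.0005` at the focal locus and
10 neutral references, then test:

```r
library(fitr)
cfg <- sim_config(builtin_model("model5", 1000), x0 = 0.5,
                  s = c(0.0005, rep(0, 10)),
                  sample_times = sampling_times(1000, 10))
traj <- simulate_replicate(cfg, seed = 42)
fitr_test(traj)
#> FITR test of neutrality
#>   statistic = 5.72931, two-sided p = 1e-05
#>   reference loci used: 10
#>   empirical null draws: 1e+05
fit_test(traj)
#> FIT test of neutrality
#>   statistic = 3.94071, df = 9, two-sided p = 0.003402
```

The focal locus climbs from 0.50 to 0.63 while the references wander
symmetrically; the FITR, whose per-interval denominator is calibrated by
the references, rejects neutrality at p = 10⁻⁵ (the smallest p-value
resolvable with 10⁵ null draws), while the FIT — inflated-variance
intervals from the bottleneck included — is an order of magnitude less
emphatic. Operating characteristics across a whole grid:

```r
rejection_rate("FITR", builtin_model("model4", 10), sampling_times(10, 2),
               R = 1, replicates = 1e4, seed = 1)
#> FITR rejection rate at alpha = 0.05: 5.13% (SE 0.22%)
#>   10000 replicates tested, 0 degenerate
#>   mean reference loci used: 1.00
```

i.e. the FITR holds its nominal 5% level even under 10⁴-fold exponential
growth, where the FIT's actual level drops to about 1%
(`rejection_rate("FIT", ...)`).

`run_table()` regenerates the full validation grids (type-I error under
models 1–5, binomial-vs-pseudo and recombination checks at small N,
low-frequency reference handling), and `power_curve()` sweeps selection
coefficients. A thin command-line front end over the same functions is
installed at `inst/cli/fitr.R` (`simulate`, `test`, `table`, `power`
subcommands) and reads/writes the TSV time-series dialect of
`read_timeseries()`/`write_timeseries()`.

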