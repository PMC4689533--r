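# tailverdict

Does a univariate sample come from a law in the **domain of attraction of
the Gaussian** (light tails, finite variance) or of a **non-Gaussian
α-stable law** (heavy tails, infinite variance)? The question decides
which limit theorem governs sums of the data, and it is notoriously hard:
a tempered (truncated) stable law, a Student's *t* law, or a slightly
skewed quadratic-Gaussian law can be practically indistinguishable from a
genuine stable law over a sample of a few thousand points, and two-sample
Kolmogorov–Smirnov tests routinely fail to separate such pairs.

`tailverdict` implements an aggregation diagnostic built directly on the
generalized central limit theorem. For block lengths *K* = 1, 2, …, 10 the
series is summed over non-overlapping consecutive blocks, and the index of
stability α of the block sums is estimated by iterative regression on the
empirical characteristic function (the stable CF is
exp{−σ^α|k|^α(1 − iβ sgn(k) tan(πα/2)) + ikμ}; stage 1 regresses
log(−log|φ̂(k)|²) on log k for α̂ and σ̂, stage 2 regresses the unwrapped
phase for μ̂ and β̂). Exactly stable data keep their index under summation,
so the curve α̂(K) stays flat below 2; any finite-variance law drifts
toward the Gaussian boundary α = 2. Bootstrap resampling of the whole
series yields per-K box plots of α̂, and a documented heuristic
(`classify_tails()`) turns the curve into a light / heavy / inconclusive
verdict. The package also ships the comparison battery (one- and
two-sample KS, Jarque–Bera, parametric-bootstrap Anderson–Darling for the
stable law) and exact or inversion-based simulators for all four law
families, packaged into five benchmark scenario pairs.

## Worked example

Generate the hardest benchmark pair — a symmetric tempered stable sample
(α = 1.9, λ = 0.1) against a symmetric stable sample (α = 1.9, σ = 1),
2000 points each — and run the full workflow:

```r
library(tailverdict)
rep <- run_report(scenario = "tempered_vs_stable", seed = 42)
print(rep)
#> tail discrimination report (seed 42 )
#>   series a: light (limiting alpha = 1.995)
#>   series b: heavy (limiting alpha = 1.963)
#>   two-sample KS on normalized pair: D2 = 0.0250, p = 0.5596

round(rep$results$a$median_curve, 3)  # tempered: drifts up and clips at 2
#>  [1] 1.961 1.973 1.982 1.989 1.990 1.999 1.996 1.997 1.995 1.994
round(rep$results$b$median_curve, 3)  # stable: plateau below 2
#>  [1] 1.934 1.939 1.945 1.950 1.950 1.950 1.955 1.963 1.961 1.965
```

Both samples have the same stable-looking bulk — the two-sample KS test on
the normalized pair is blind (p = 0.56) — but aggregation exposes them:
the tempered sample's estimated index climbs to the α = 2 line (it has
finite variance, so its block sums Gaussianize), while the stable sample's
index stays on a plateau below 2. `run_report(..., out_dir = "out/")`
additionally writes a JSON report, per-K box-plot statistics as TSV, and
PNG figures (per-K box plots and log-log empirical tails).

For your own data: `load_series("x.txt")` (or a CSV column), then
`bootstrap_curves()`, `classify_tails()`, `tail_plot()` — or the thin CLI
in `inst/cli/tailverdict.R`:

```sh
Rscript inst/cli/tailverdict.R discriminate --input x.txt --out out/
Rscript inst/cli/tailverdict.R compare --a x.txt --b y.txt
```

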