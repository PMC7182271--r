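# radkrige

Iterative geostatistical dose mapping for population-scale radiation
events.

After a nuclear detonation or large radiological release, absorbed doses
cannot be measured for everyone: dosimetry and biodosimetry throughput are
far below population scale, and every field excursion exposes first
responders. `radkrige` reconstructs the spatial dose distribution — in
particular the territory where exposure reaches the 2 Gy
treatment-eligibility threshold for Acute Radiation Syndrome triage — from
measurements at a small, adaptively chosen fraction of locations:

1. draw random sampling locations in each population subdivision
   overlapping or surrounding the suspected plume, proportional to
   population (default 0.1%);
2. krige a dose surface with prediction standard errors
   (ordinary/simple/universal kriging, or an empirical Bayesian kriging
   ensemble approximation);
3. densify: dispatch up to 200 new sampling locations where the map is
   least certain among cells whose upper-quartile predicted dose
   (`prediction + 0.6745·SE`) reaches the 2 Gy threshold;
4. repeat until consecutive maps agree: the eight dose bands
   (<1, 1–2, …, 6–7, >7 Gy) of successive surfaces are compared through an
   overlap heat matrix whose diagonal `A_i` feeds two stopping statistics,

   ```
   BCD  = Σ|1 − A_i| / Σ(1 + A_i)        (diagonal Bray–Curtis dissimilarity)
   RMSD = sqrt( mean( (1 − A_i)² ) )
   ```

   with stopping when either drops strictly below its 90%-overlap
   threshold (BCD < 1/19, RMSD < 0.1; a 99% stringency mode uses 1/199 and
   0.01).

A synthetic scenario generator (nested 0.5 Gy dose-contour rings from an
analytic teardrop field, census-like subdivision maps with uniform
within-subdivision density) makes the whole pipeline testable end to end,
and population-weighted accuracy scoring grades reconstructions against
that ground truth. Intended users: radiation-emergency preparedness and
biodosimetry researchers studying sampling protocols, and anyone needing a
self-contained, seeded testbed for adaptive spatial sampling methods.

## Worked example

```r
library(radkrige)

cfg <- scenario_config(grid_n = 150)   # reference urban scenario
run <- run_replicate(cfg, seed = 101, verbose = TRUE)
print(run)
print(run$trace)
```

```
iteration 1: 2672 samples (220 irradiated)
iteration 2: +96 samples, BCD 0.0690, RMSD 0.1426
iteration 3: +99 samples, BCD 0.0486, RMSD 0.1058
Replicate run (seed 101): converged after 3 iterations (bcd)
  samples: 2867 total, 415 irradiated; bearing error 22.3 deg
  recall >=2 Gy: 92.2%, >=3 Gy: 92.2%; FP fraction 0.00%
  iteration n_samples n_new        bcd      rmsd
1         2      2768    96 0.06904340 0.1425772
2         3      2867    99 0.04858897 0.1058131
```

Reading this: the initial 0.1% draw placed 2672 samples in the eligible
subdivisions, 220 of them inside the plume. Two densification rounds of
~100 locations each were enough for the band overlap between consecutive
maps to exceed 90% (BCD 0.049 < 1/19 stops the loop), leaving 415
irradiated samples in total. The converged map captures 92% of the
population truly at ≥2 Gy while almost none of its flagged population is
below the threshold.

Scenario-level runs (`run_scenario`) repeat this over replicate seeds and
compare replicate plumes pairwise; `run_perturbation_suite` crosses dose
measurement error (±0.5 / ±1.0 Gy) with directionally biased sampling
(`wind_bias_fractions`, e.g. 0.05%:0.2% splits emulating a wind-bearing
error). A thin CLI over these functions lives at `inst/cli/radkrige.R`
(subcommands `simulate`, `run`, `perturb`, `report`; flat YAML configs).

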