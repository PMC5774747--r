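# autoplanr

Automated inverse optimization for radiotherapy planning by stepwise
reduction of dose-volume objectives.

Inverse planning is usually a trial-and-error loop: a planner adjusts
organ-at-risk (OAR) dose-volume objectives by hand until the plan balances
target coverage against normal-tissue dose. `autoplanr` implements a fully
automated version of that loop as a tested, self-contained R engine: it
starts from the best achievable target plan and then iteratively tightens
the OAR objectives — buying normal-tissue sparing with target-dose
homogeneity — until a prescribed heterogeneity budget over the target is
spent. It is aimed at medical-physics researchers who want to study
planning-automation controllers with transparent, reproducible components
rather than a commercial treatment-planning system.

## The method

All objectives are weighted, volume-normalized quadratic penalties of the
form

    F_j = w_j * sum_{i in V} ((d_i - d_j) / d_j)^2 * dv_i

where `V` is the set of offending voxels of the bound structure (for an
overdose objective, those with dose `d_i` above the objective dose `d_j`),
`w_j` the weight, and `dv_i` the voxel volume normalized by the structure
volume. Dose is linear in the beamlet fluence, `d = D x` with `x >= 0`,
with `D` a sparse pencil-beam dose-influence matrix; fluence is optimized
by a monotone projected-gradient method (Barzilai-Borwein trial steps,
Armijo backtracking).

The automated controller:

1. generates concentric **ring** structures around the target to shape the
   dose fall-off, and fixed target (min/max/uniform dose, weight 100) and
   ring (max/mean dose, weight 80) objectives;
2. optimizes the fluence against those objectives only and normalizes so
   that D95 of the target equals the prescription (default 35 Gy to 95%);
3. samples each OAR's cumulative DVH at five equispaced fractional volumes
   (1% to 70%) to seed one DVH objective per point (weight 1);
4. adjusts each OAR objective dose `d_j` (by bisection on the penalty) so
   its objective value sits 5% above the largest target objective value;
5. re-optimizes from the reset fluence with all objectives, renormalizes,
   and tests the termination criterion: the population standard deviation
   of the target dose, relative to the prescription, reaching 5%;
6. repeats steps 4-5 — OAR objective doses are clamped so they only ever
   decrease — and returns the last plan whose heterogeneity stayed within
   the budget.

Deterministic voxel phantoms (a target abutted by a serial OAR, with a
distant serial OAR and two lateral parallel OARs, emulating the pancreatic
SBRT situation) are built in, so the whole engine runs without any patient
data or external dose engine. Plan quality is tallied with the usual dose
indices (D95, D5, D2%, Dmean) and paired plans can be compared with
normalized dose-index ratios and the exact Wilcoxon signed-rank test.

## Worked example

```r
library(autoplanr)

phantom <- build_reference_phantom("pancreas2d", seed = 0)
plan <- run_autoplan(phantom, autoplan_config())
print(plan)
#> autoplan_result: 6 cycle(s), sigma limit; final PTV sigma = 4.17% of 35 Gy
#>   structure         role          D95         D2      Dmean       Dmax sigma_pct
#> 2       ptv       target 35.000000000 39.3925285 36.3132904 39.3925285  4.1727738
#> 3  duodenum   oar_serial  0.006686358  6.8664458  1.0944849  6.8664458  5.0264335
#> 4      cord   oar_serial  0.318933810  0.6309569  0.4697691  0.6309569  0.3360915
#> 5  kidney_l oar_parallel  0.159505198  0.5311611  0.3378090  0.5323363  0.3041529
#> ...

plan$trace[, c("cycle", "sigma_pct", "composite", "terminated")]
#>   cycle sigma_pct  composite terminated
#> 1     0  1.804176 0.03530111      FALSE
#> 2     1  2.014374 0.06024284      FALSE
#> 3     2  2.333499 0.07734068      FALSE
#> 4     3  2.774201 0.12975151      FALSE
#> 5     4  3.434627 0.26041006      FALSE
#> 6     5  4.172774 0.47370219      FALSE
#> 7     6  5.622752 0.97034365       TRUE

duo <- get_structure(plan$structures, "duodenum")$voxels
dose_quantile(plan$initial$dose[duo], 2)   # near-max dose, target-only plan
#> [1] 26.91 Gy
dose_quantile(plan$dose[duo], 2)           # after automated DVH reduction
#> [1] 6.87 Gy
```

Reading the output: cycle 0 is the target-plus-rings plan — very
homogeneous (standard deviation 1.8% of the 35 Gy prescription) but with
the abutting duodenum at 26.9 Gy near-maximum dose. Each cycle lowers the
OAR objective doses and re-optimizes; target heterogeneity rises stepwise
while OAR dose falls. Cycle 6 overshoots the 5% budget, so the delivered
plan is cycle 5: D95(PTV) held at exactly 35 Gy, target standard deviation
4.17%, and the duodenum near-maximum dose reduced to 6.9 Gy. Every cycle's
objective doses, objective values and heterogeneity are kept in
`plan$trace` and `plan$objective_history`.

Command-line wrappers for phantom generation and planning live in
`inst/cli/` (`phantom.R`, `autoplan.R`); phantoms are stored as NIfTI
masks with a JSON manifest, plans export to NIfTI/CSV/JSON-lines.

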