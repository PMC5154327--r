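# fearext

Simulation and analysis of differential fear conditioning/extinction
psychophysiology, for researchers who score event-related skin conductance
responses (SCRs) and test whether a continuous trait — here Intolerance of
Uncertainty (IU) — moderates extinction learning.

In the paradigm this package implements, a CS+ cue is paired with an
aversive sound 100% of the time during a 24-trial acquisition block while a
CS− never is; a 32-trial extinction block presents both unreinforced.
Responding is measured two ways: trial-locked SCR amplitudes (trough-to-peak,
µS) and 1–9 uneasiness ratings. The package provides, as plain R functions
under numbered analysis scripts:

* **Task design** — pseudo-randomized trial sequences (condition runs ≤ 3),
  counterbalanced cue colours, jittered timing (cue 1.5 s, blank 3.0–6.45 s,
  rating 4 s, blank 1.0–2.5 s).
* **Synthetic cohorts with ground truth** — correlated IU/STAIX-2/PSWQ
  panels; electrodermal recordings built from a bi-exponential SCR kernel
  with per-trial amplitudes `max(0, m_cell + b_cell·z_IU + ε)`, zero-inflated
  at the observed rates (33% acquisition, 53% extinction) and calibrated so
  sqrt-scale cell magnitudes match the published table; ordinal ratings;
  optional two-channel motion artifacts.
* **SCR scoring** — smoothed trough-to-peak detection with a 0.03 µS
  threshold and a 0–7 s onset window, first-trial exclusion, conjunctive
  EDA+pulse artifact flagging, square-root transform, and condition × time
  magnitude cells (first 8 vs last 8 extinction trials per condition, zeros
  included).
* **Learning assessment** — conditioned-response score (first 2 CS+ − first
  2 CS− extinction trials) per measure; non-learner iff both ≤ 0.
* **Statistics** — Condition × Time × IU repeated-measures ANCOVA via
  orthogonal contrast scores regressed on the mean-centered moderator
  (F on (1, n−2) df), partial η² = F/(F+df2), estimated marginal means and
  simple-slopes contrasts at IU ± 1 SD, and hierarchical regressions
  (STAIX-2 + PSWQ, then IU) with ΔR² and F-change.

## Worked example

```r
library(fearext)
run <- run_pipeline(n_subjects = 38, seed = 5)
run$analyses$scr_extinction
```

```
Repeated-measures ANCOVA (condition_by_time), n = 38, moderator = iu (SD = 21.58)

                effect       F df1 df2         p partial_eta_sq
             Condition  7.0226   1  36 0.0118825       0.163231
        Condition x IU  3.3898   1  36 0.0738534       0.086058
                  Time  5.6830   1  36 0.0225241       0.136339
             Time x IU  0.1422   1  36 0.7083649       0.003933
      Condition x Time  3.0659   1  36 0.0884680       0.078481
 Condition x Time x IU 14.4434   1  36 0.0005374       0.286329
                    IU  2.6557   1  36 0.1118981       0.068702
```

The three-way interaction says the Condition × Time pattern depends on IU.
The follow-up contrasts, estimated from the whole-sample fit at IU ± 1 SD:

```r
run$simple_slopes
```

```
                 contrast at_sd estimate     se       t df        p
 CSplus - CSminus (early)    -1  0.05645 0.0455  1.2410 36 2.23e-01
  CSplus - CSminus (late)    -1 -0.02731 0.0307 -0.8897 36 3.80e-01
    early - late (CSplus)    -1  0.08568 0.0275  3.1161 36 3.59e-03
   early - late (CSminus)    -1  0.00192 0.0433  0.0444 36 9.65e-01
 CSplus - CSminus (early)     1 -0.02779 0.0455 -0.6109 36 5.45e-01
  CSplus - CSminus (late)     1  0.19562 0.0307  6.3730 36 2.21e-07
    early - late (CSplus)     1 -0.08000 0.0275 -2.9095 36 6.17e-03
   early - late (CSminus)     1  0.14341 0.0433  3.3142 36 2.10e-03
```

Estimates are sqrt-µS differences. At low IU (−1 SD) the CS+/CS−
differential is positive early and gone late; at high IU (+1 SD) the late
differential is large (0.196 sqrt-µS, p < .001) and the CS− response drops
from early to late (0.143, p = .002) — the threat-generalization /
compromised-safety-learning signature the generator encodes. Single
cohorts vary: `run_calibration_study()` puts sign-pattern recovery at
roughly 85–90% of replicates and the type-I error of the three-way test at
its nominal 0.05. This run classified 33 of 38 subjects as learners and
excluded none.

The analysis workflow runs the same stages as scripts, writing CSV tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_score.R
Rscript analysis/03_assess_learning.R
Rscript analysis/04_analyze.R
Rscript analysis/05_calibrate.R
```

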