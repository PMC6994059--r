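---
title: "Methods: the precision-fed rooster assay calculations in pfda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the precision-fed rooster assay calculations in pfda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfda)
```

## The assay and its model

In a precision-fed assay, a rooster is fasted, crop-intubated with a
fixed dose of the test food (20 g dry matter here), and its excreta are
collected quantitatively for 48 h. Because the bird received a known dose
and nothing else, intake of every nutrient is known exactly
(dose × concentration), and digestibility reduces to an input–output
balance. Cecectomized birds are used for nutrient and amino-acid
digestibility so that hindgut microbial fermentation does not inflate the
estimates; conventional birds are used for the energy balance. Fasted
birds excrete material of body origin (sloughed cells, endogenous
secretions, maintenance nitrogen); subtracting that **endogenous loss**
converts apparent digestibility into *true* (also called *standardized*)
digestibility:

$$d = 100 \cdot \frac{\mathrm{intake} - (\mathrm{excreted} - \mathrm{endogenous})}{\mathrm{intake}}.$$

`pfda` implements this in one routine (`true_digestibility()`);
`endogenous = 0` gives the apparent value. The terms "true" and
"standardized" both refer to this fasted-bird correction and are used
interchangeably here. The endogenous amount for each analyte is the
across-bird mean of the five fasted reference birds, computed once per
assay and applied uniformly — there is no defensible per-bird matching
rule for birds that never received the diet.

The nitrogen-corrected true metabolizable energy of a diet, per bird, is

$$\mathrm{TMEn} = \frac{EI_{fed} - (EE_{fed} - k\,N_{fed}) + (EE_{fasted} - k\,N_{fasted})}{FI},$$

with $EI_{fed}$ the gross-energy intake of the dose (kcal), $EE_{fed}$
the 48-h excreta energy, $N_{fed}$ the excreta nitrogen (g),
$k = 8.22$ kcal/g the energy equivalent of uric acid per gram of
nitrogen, and $FI$ the dose (g DM). The nitrogen terms remove the energy
cost of nitrogen that was retained rather than excreted as uric acid, so
that diets are compared at nitrogen equilibrium; the fasted terms
($EE_{fasted} = 16.74$ kcal, $N_{fasted} = 1.1256$ g per bird per 48 h,
long-run constants) perform the same apparent-to-true correction as
above. Printed versions of this equation sometimes carry ambiguous
plus–minus signs and label $EE_{fasted}$ per gram; the implementation
uses the canonical balance above, in which $EE_{fasted}$ must be a total
energy. Two checks pin the sign convention down: when a fed bird's
excreta are indistinguishable from fasting losses
($EE_{fed} = EE_{fasted}$, $N_{fed} = N_{fasted}$) TMEn equals the
diet's gross energy exactly, and realistic inputs land in the measured
4.6–5.9 kcal/g range. All three constants are overridable through
`endogenous_constants()`.

## Composition accounting and the three ME systems

All nutrient concentrations are carried on the 0–100 percent scale on a
dry-matter basis; the dry-matter content of the as-is food is metadata
only. Nitrogen-free extract — the by-difference carbohydrate estimate —
uses total dietary fiber (TDF), not crude fiber, as the fiber term:

$$\mathrm{NFE} = 100 - (\mathrm{CP} + \mathrm{AHF} + \mathrm{TDF} + \mathrm{ash}).$$

NFE is *always recomputed* from the components. A printed NFE column in
an input file is cross-checked (warning at |Δ| > 0.05) but never used,
so the downstream energy equations stay consistent with their own
inputs. This matters at the rounding margin: the shipped composition
table is printed at 0.01 precision, and the recomputed NFE differs from
the printed row by 0.01 for five of the six diets. Tests and the
acceptance checks therefore use a ±0.02 band for NFE and carry the
recomputed value forward.

The three prediction systems are:

* **Atwater** (4 / 9 / 4 kcal/g for protein / fat / carbohydrate):
  assumes human-food digestibility (~91/96/96%).
* **Modified Atwater** (3.5 / 8.5 / 3.5): assumes conventional pet-food
  digestibility (~80/90/85%), so it systematically undershoots highly
  digestible diets.
* **NRC fiber chain**: predicted
  $GE = 5.7\,\mathrm{CP} + 9.4\,\mathrm{AHF} + 4.1(\mathrm{NFE} + \mathrm{TDF})$
  kcal/100 g; energy digestibility
  $ED = 91.2 - 1.43\,\mathrm{TDF}$ (%); $DE = GE \cdot ED / 100$;
  $ME = (DE - 1.04\,\mathrm{CP})/100$ kcal/g. Intermediates are per
  100 g DM, mirroring the equation chain; only the final step is per
  gram. $ED$ is clamped to [0, 100] with a warning — TDF above 63.8%
  would drive it negative — and the clamp is never silent.

### A reproducibility caveat on the NRC row

The published table this package ships reports an "ME (NRC equation)"
row (e.g. BRP 5.83, CWR 4.37 kcal/g) that is **not reproducible** from
the published equation chain applied to the published composition: the
recomputation gives BRP 5.54 and CWR 4.10. `pfda` implements the
equations, not the transcribed row; `compare_me_systems()` carries a
note stating that its NRC column is the recomputed chain. The
constants were deliberately not adjusted to chase the printed row, and
the discrepancy is asserted (not hidden) in the test suite.

### TMEn/GE averaging

TMEn/GE (%) is reported per bird and then averaged. Because gross energy
is a single diet-level measurement, the per-bird mean of
$100\,\mathrm{TMEn}_i/GE$ is algebraically identical to the ratio of the
means, so the report prints both columns and they coincide on any data
this package produces. The published ratios for two diets sit 0.1 point
away from the ratio of the printed means (e.g. 4.71/5.37 = 87.7 vs a
printed 87.8); that offset is a rounding artifact of the printed TMEn
means, and the consistency checks use a ±0.15 band for those two diets
accordingly.

## Statistics

Each analyte is analyzed as a one-way completely randomized design:
substrate fixed, one observation (bird) per experimental unit. With a
single observation per bird, a random bird effect is not separable from
the residual, so the mixed model reduces *exactly* to one-way
fixed-effects ANOVA — `crd_anova()` states this reduction rather than
emulating any particular mixed-model software. The pooled SEM is
$\sqrt{MSE/n}$ under balance (the design here is balanced at $n = 4$);
for unbalanced data the harmonic-mean $n$ is used with a warning.

Tukey's HSD compares all pairs on the studentized-range scale,
$q = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}$, with
adjusted p-values from `ptukey` at $(k, \mathrm{df}_2)$; $\alpha = 0.05$
by default, overridable. The compact letter display uses the
insert-and-absorb algorithm: start with one letter covering all groups,
split every letter containing both members of a significant pair, then
drop letters that became subsets of another. Two groups share a letter
if and only if they are not significantly different; the representation
is exact for any pattern, including non-transitive ones, and the test
suite verifies this round-trip against brute-force enumeration of *all*
significance patterns up to five groups, plus an independent
cross-check against `multcomp::cld`. Letters are ordered a, b, c, … by
descending group mean, ties broken lexicographically by group label, so
output is deterministic.

Degenerate inputs are handled explicitly: identical groups give
$F = 0, p = 1$; zero within-group variance with unequal means is flagged
(`degenerate = TRUE`) with $p$ reported as the smallest positive double
rather than an unstable floating-point ratio. Digestibility values above
100% (endogenous correction exceeding excretion, expected occasionally
in noisy data) are reported with a warning and never truncated, so group
means stay unbiased.

## The synthetic generator

`assay_scenario()` / `simulate_assay()` invert the estimation equations
around known truths: per bird, expected excretion is
$\mathrm{intake}(1 - d/100) + \mathrm{endogenous}$ for each analyte, and
fed-bird excreta energy is solved from the TMEn balance given the diet's
true TMEn. Additive Gaussian noise is then applied to every excreta
amount, negatives are truncated at zero (counted, with a warning above a
10% truncation rate). Defaults reproduce the packaged study: 6 diets,
4 birds per substrate, 5 fasted birds, a 20 g DM dose, with true
digestibilities and TMEn set to the packaged reported means.

Per-bird noise magnitudes are not published, so the defaults are
conventions, chosen once so that simulated pooled SEMs land in the
magnitude range of the published SEM columns (≈0.8–2.2): excreta DM
0.8 g, OM 0.7 g, AHF 0.06 g, excreta energy 2.0 kcal, nitrogen 0.08 g,
and 0.009 g for each amino acid. A single additive SD per analyte class
means low-concentration amino acids (cysteine, taurine) get a larger
digestibility scatter than abundant ones — visible in the published SEM
column too, where cysteine is the noisiest row. Fasted-bird amounts are
drawn around the endogenous means (DM 4.0 g, OM 3.2 g, AHF 0.25 g,
energy 16.74 kcal, N 1.1256 g, 0.015 g per amino acid) with half the fed
noise scale, reflecting that fasted birds excrete roughly half the mass;
because the endogenous mean is shared by every bird in an assay, its
sampling noise adds between-assay variance that the within-assay SEM
cannot reflect, and the halved scale keeps the estimator's replicate-
to-replicate SD within 20% of the reported pooled SEM. Fed-bird excreta
nitrogen is placed using a true nitrogen digestibility of 85%, typical
of the measured amino-acid digestibilities. Taurine appears in the
concentration table but has no published digestibility, so the default
scenario simulates the 18 amino acids with truths.

Reproducibility: each bird's random stream is seeded deterministically
from (seed, diet index, bird index, assay role), so the same seed gives
byte-identical output and a smaller scenario reproduces the leading
birds of a larger one exactly.

What the generator does **not** emulate: digestive physiology (no
saturation, no fiber–nutrient interactions), correlated errors across
analytes within a bird, dose refusal or regurgitation losses, and any
skew in the noise (a lognormal option was considered and not
implemented; excreta amounts sit far enough from zero at the default
SDs that skew is immaterial, but heavy-tailed real data would not be
represented). Passing the recovery tests therefore demonstrates that the
estimation chain is a correct inverse of this statistical model — not
that real assay data satisfy the model.

## Problem sizes and numerical tolerances

The simulation-based guarantees are checked at fixed sizes chosen to
make Monte-Carlo error small relative to the asserted bounds: 2,000
simulated null experiments (k = 6, n = 4) for the familywise type-I
error of the Tukey procedure, asserted within [0.035, 0.065]
(binomial SE ≈ 0.005 at 2,000); 500 simulated assays at default noise
for recovery, asserted |bias| < 0.5 percentage points for DM
digestibility and < 0.05 kcal/g for TMEn (the Monte-Carlo SEs are an
order of magnitude below both bounds); 500 replicates for the
SD-vs-SEM consistency check at a 20% band. Zero-noise inversion is
asserted at 10⁻¹² relative; the TMEn cancellation identity at machine
precision. The k = 2 equivalences (F = t², Tukey p = t-test p) are
asserted at 10⁻⁴ relative because `ptukey` is itself only accurate to
about 10⁻⁸ absolute.

## Known limitations

* Per-bird raw data for the packaged study are not published, so its
  digestibility means and SEMs cannot be reproduced exactly; they enter
  as generator truths, and the package's claims about them are recovery
  and calibration properties, not reproductions.
* The NRC-row discrepancy described above is documented, not resolved.
* The noise model is additive Gaussian with per-analyte constants;
  amino-acid SEM magnitudes are matched only in order of magnitude.
* The statistics module covers the one-way completely randomized design
  only — no repeated measures, no Latin squares, no REML variance
  components.
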