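# pfda — precision-fed rooster digestibility and metabolizable energy

`pfda` implements the computational chain behind precision-fed
(crop-intubated) cecectomized rooster assays of complete pet foods. Assay
labs and pet-food researchers use this design to measure, per diet, the
true (endogenous-corrected) digestibility of macronutrients and amino
acids and the nitrogen-corrected true metabolizable energy (TMEn), and to
ask whether label-style energy predictions track the measured energy. The
package covers:

- **Composition accounting** on a dry-matter basis (DMB): validation,
  nitrogen-free extract by difference using total dietary fiber,
  `NFE (%) = 100 − (CP + AHF + TDF + ash)`.
- **Three ME prediction systems**:
  Atwater `ME = (4·CP + 9·AHF + 4·NFE)/100` kcal/g,
  modified Atwater `ME = (3.5·CP + 8.5·AHF + 3.5·NFE)/100`, and the NRC
  fiber-based chain
  `GE = 5.7·CP + 9.4·AHF + 4.1·(NFE + TDF)`,
  `ED (%) = 91.2 − 1.43·TDF`, `DE = GE·ED/100`,
  `ME = (DE − 1.04·CP)/100`.
- **TMEn** per bird,
  `TMEn = [EI_fed − (EE_fed − 8.22·N_fed) + (EE_fasted − 8.22·N_fasted)]/FI`,
  with the long-run fasted-bird constants `EE_fasted = 16.74` kcal and
  `N_fasted = 1.1256` g per 48 h and the uric-acid factor 8.22 kcal/g N.
- **True/standardized digestibility**,
  `100·[intake − (excreted − endogenous)]/intake`, with the endogenous
  term taken as the mean of five fasted reference birds.
- **Study statistics**: one-way ANOVA of the completely randomized design
  (4 birds per substrate), pooled SEM `sqrt(MSE/n)`, Tukey HSD via the
  studentized-range distribution, and a compact letter display
  (insert-and-absorb).
- **A synthetic assay generator** that inverts the equations above around
  known true parameters, so the entire pipeline is testable with no
  animal data.

The package ships the composition, amino-acid, and reported-results
tables of a six-diet study of human-grade dog foods (diets BRP, CWR, FSP,
LBR, TWM, VSR) as plain-CSV fixtures; these are the default study
conditions everywhere.

## Worked example

```r
library(pfda)

fx <- fixture_tables()
print(fx$composition)
#> Diet composition (% DM basis), 6 diet(s)
#>  diet_id dm_pct  ash    cp   ahf   tdf  tif  tsf   ge   nfe
#>      BRP  92.89 4.16 31.14 46.40  4.22 3.91 0.30 6.69 14.08
#>      CWR  93.92 3.82 29.10 17.27  5.92 4.45 1.47 5.19 43.89
#>      ...

tmen_means <- setNames(c(5.83, 4.75, 4.71, 4.89, 4.71, 4.62),
                       fx$composition$diet_id)
cmp <- compare_me_systems(fx$composition, tmen_means)
subset(cmp, diet_id %in% c("BRP", "CWR"))
#>  diet_id           system   me tmen deviation direction
#>      BRP          atwater 5.98 5.83      0.15      over
#>      CWR          atwater 4.47 4.75     -0.28     under
#>      BRP modified_atwater 5.53 5.83     -0.30     under
#>      CWR modified_atwater 4.02 4.75     -0.73     under
#>      BRP              nrc 5.54 5.83     -0.29     under
#>      CWR              nrc 4.10 4.75     -0.65     under
```

Reading the deviations: every prediction system underestimates the
measured energy of CWR (and likewise FSP, TWM, VSR); only Atwater, built
for highly digestible human foods, lands above TMEn for the very
fat-dense BRP. The `nrc` column is the published equation chain
*recomputed from composition* — see the vignette for why a transcribed
NRC row can disagree with its own equations.

A full pipeline run on a simulated assay (composition report, per-bird
digestibility and TMEn, Tukey letters, report tables):

```r
rep1 <- run_pipeline(pipeline_config(seed = 42))
rep1$tables$energy
#>   analyte   BRP   CWR    FSP   LBR    TWM   VSR   SEM p_value
#> 1    TMEn 5.70a 4.69c 4.75bc 4.87b 4.72bc 4.66c 0.039 <0.0001
#> 2 TMEn/GE 85.3b 90.4a 88.5ab 86.5b 87.4ab 85.7b 0.722  0.0008
```

Means within a row lacking a common letter differ at P < 0.05; `SEM` is
the pooled standard error of a group mean. With `out_dir` set,
`run_pipeline()` writes the same tables as TSV plus a JSON run manifest.

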