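# bispbk

Physiologically based kinetic (PBK) models for bisphenol A and six of its
structural analogs (BPAF, BPB, BPE, BPF, BPM, BPS) after oral exposure, for
toxicokinetic modellers and risk assessors who need internal-exposure
estimates for chemicals with little or no human in vivo data.

Bisphenol substitutes are widespread in food-contact materials, yet their
absorption, distribution, metabolism and excretion are mostly
uncharacterised in humans. `bispbk` implements a two-layer compartmental
model — the parent compound and its glucuronide conjugate — over a
flow-limited perfusion network (gut lumen and wall, liver, kidney, thyroid,
testes or breasts, lumped slowly/rapidly perfused tissue, blood) for a rat
model and four human physiologies (man, woman, child, toddler). Each tissue
obeys

    V_i dC_i/dt = Q_i (C_blood − C_i / Kp_i)

with saturable hepatic glucuronidation v = Vmax·C/(Km + C), first-order
gastric emptying and intestinal uptake (ka = 2·Peff/R), enterohepatic
recirculation of the glucuronide (biliary clearance QL·EHCr, instant
luminal deconjugation and reabsorption), glomerular filtration of the
unbound parent, and EHCr-scaled renal efflux secretion of the glucuronide.

Because the analogs are data-poor, the model family is parametrized
multimodally rather than calibrated to human data:

* Caco-2 apparent permeabilities (measured and QSAR-predicted, pooled with
  equal weight) scaled to effective jejunal permeability with the published
  "all drugs" log-log regression;
* glucuronidation kinetics fitted from in vitro substrate-depletion curves
  (Michaelis–Menten vs substrate inhibition, Nalimov outlier screening,
  best fit by R², whole-liver scaling by system-matched protein yields,
  UGT2B15 ontogeny scaling for child/toddler);
* tissue:blood partition coefficients assembled from per-organ inputs
  (volume-weighted lumping; breast = 0.245 × adipose);
* the enterohepatic recirculation rate fitted against late-time rat blood
  data and transferred across chemicals by glucuronide molecular weight.

On top of the simulator sit exposure scenarios (single and repeated
dietary dosing), mass-balance and clearance diagnostics, 2-fold predictive
evaluation against packaged human observations, local sensitivity
coefficients, Morris screening, eFAST variance decomposition, and
constrained Monte Carlo uncertainty propagation.

## Worked example

Simulate a single dietary-level BPA dose (336 ng/kg bw) in the adult male
model and inspect the diagnostics:

```r
library(bispbk)

params <- default_pbk_params("BPA", "man")
sim    <- simulate_pbk(params, make_schedule(5))

mass_balance(sim)
#>   time_h urinary_pct fecal_pct retained_pct urinary_parent_pct
#> 1     12        90.4      5.89     3.72                0.00511
#> 2     24        93.8      6.07     0.103               0.00536
#> 3     48        93.9      6.08     0.0000795           0.00536

clearance_report(params, sim)
#>    cl_r cl_bile ratio_bile_renal bile_to_plasma f_app
#> 1  9.68    16.7             1.72           572.  2.64
```

Read: ~90% of the dose is in urine within 12 h, almost entirely as the
glucuronide (unconjugated parent ≈ 0.005%); biliary clearance (16.7 L/h)
exceeds renal clearance (9.7 L/h) 1.7-fold, the glucuronide is ~570-fold
concentrated in bile over plasma, and the apparent absorbed fraction of
2.6 means the average absorbed molecule cycles through bile and gut about
1.6 extra times before leaving — the signature of extensive enterohepatic
recirculation.

Replicating a controlled 30 µg/kg oral BPA study with uncertainty:

```r
mc <- monte_carlo_pbk(default_pbk_params("BPA", "man"), make_schedule(3),
                      n_draws = 1000, seed = 1, analyte = "glucuronide")
glance(mc)
#>   n_draws  seed cmax_median cmax_q1 cmax_q3 auc_median
#> 1    1000     1        183.    150.    218.       39.2
autoplot(mc)
```

The median glucuronide blood peak is ~183 nM (IQR 150–218). Evaluating all
blood metrics for BPA and BPS against the packaged human observations:

```r
Rscript inst/cli/bispbk evaluate
#> within 2-fold: 66.7% of 12 comparisons
```

A thin command line (`inst/cli/bispbk`) exposes `simulate`, `massbalance`,
`evaluate`, `mc`, `sensitivity`, `fit-kinetics`, `fit-ehc` and `pipeline`
subcommands over the same functions.

All shipped parameter tables are self-contained defaults (standard
reference physiology; synthetic, clearly-labelled chemical inputs of
realistic magnitude). Supply your own tables of the same shape —
`load_chemical_table()`, `default_kp_table()`-shaped Kp values,
depletion data for `fit_glucuronidation()`, rat blood data for
`fit_ehcr_rat()` — for quantitative work; see the methods vignette
(`vignettes/bisphenol-pbk-methods.Rmd`) for every default and the
reasoning behind it.

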