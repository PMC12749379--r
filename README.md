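# fescycle

Kinematic modelling and stimulation-pattern design for functional
electrical stimulation (FES) cycling in rats.

FES cycling drives pedaling by electrically stimulating peripheral nerves
and muscles, and is studied as a rehabilitation modality for muscle and
bone recovery after neurologic injury. Rodent models accelerate that
research, but they need the same ingredient human FES bikes have: a
kinematic model that tells the controller *at which crank angles* each
muscle group or nerve should be stimulated so its evoked torque actually
drives the crank forward (or backward), instead of fighting it. This
package is for researchers building or analysing such rat FES-cycling
systems: it implements the hindlimb model, derives the stimulation
patterns, and provides the full validation pipeline for scoring modelled
regions against stimulation-trial data — including a seeded synthetic-trial
generator, so everything runs and is testable without animal data.

## The model in brief

The hindlimb on the bicycle is a one-degree-of-freedom closed kinematic
chain parameterised by the encoder's crank angle $q$. With the link
lengths known, the ankle angle has a closed form
($q_a = -\arctan\left(l_c\cos u \,/\, (l_c \sin u + d)\right)$, with $u$ the
internal chain parameter), and the hip and knee angles follow from the
two-link closure (arccosine form, keeping the non-hyperextended branch;
two-argument arctangent for the knee). Differentiating the closure gives
the joint-velocity transforms $S_a, S_h, S_k = \mathrm{d}q_j/\mathrm{d}q$,
and the principle of virtual work turns them into torque-transfer ratios

$$T_\mathrm{hip} = S_h,\qquad T_\mathrm{knee} = -S_h + S_k,\qquad
T_\mathrm{ankle} = S_h - S_k + S_a,$$

the dimensionless leverage each joint torque has on the crank. Stimulation
regions are threshold sets of these ratios, e.g. the femoral-nerve region
$\mathcal{Q}_{fn} = \{q : -T_\mathrm{knee} > \epsilon_{fn}\}$ and the
sciatic-nerve region
$\mathcal{Q}_{sn} = \{q : a_1 T_\mathrm{hip} + a_2 T_\mathrm{knee} + a_3
T_\mathrm{ankle} > \epsilon_{sn}\}$, made disjoint so antagonists are never
co-stimulated. Experimental regions of activity (RoAs) are estimated as
the shortest circular arc capturing 95 % of motion-positive trials, and
model–experiment agreement is scored on angular measure: TP/TN/FP/FN arcs
partitioning the circle, then sensitivity, specificity, PPV and NPV. The
methods vignette (`vignettes/fescycle-methods.Rmd`) documents every
convention, default and design decision.

## Worked example

```r
library(fescycle)
geom <- default_geometry()

print(torque_transfer(c(45, 135, 225, 315), geom), digits = 3)
#>   crank_angle    S_a     S_h    S_k   T_hip T_knee T_ankle
#> 1          45 -0.266 -0.0638 -0.673 -0.0638 -0.609   0.344
#> 2         135 -0.266  0.2710 -0.467  0.2710 -0.738   0.472
#> 3         225  0.207  0.1858  0.796  0.1858  0.610  -0.403
#> 4         315  0.207 -0.6840  0.129 -0.6840  0.813  -0.606
```

At 45° and 135° the knee ratio is strongly negative: knee extension
(quadriceps, i.e. femoral-nerve stimulation) drives the crank clockwise
through the first half of the cycle. Thresholding the profiles yields the
two-nerve pattern:

```r
nerve_regions(geom, pattern_config(), "cw")
#> Stimulation pattern, version B, cw, right leg
#>   fn   eps=0.1009  [7.7, 191.9)
#>   sn   eps=0.1337  [191.9, 246.1)
```

The femoral nerve is stimulated over roughly the first half-turn, the
sciatic nerve over the following arc, and the regions are disjoint. The
full validation chain on a synthetic 720-trial campaign:

```r
sim <- run_simulate(seed = 42, geom = geom, out_dir = tempdir())
met <- run_validate(sim$trials, geom)
run_report(met)
#> ...
#> Summary (mean +/- sample SD (range)):
#>   sensitivity 0.7869 +/- 0.264 (0.301-1), n=8
#>   specificity 0.9563 +/- 0.0486 (0.8669-1), n=8
#>   ppv         0.8878 +/- 0.143 (0.5917-1), n=8
#>   npv         0.9023 +/- 0.136 (0.5886-1), n=8
```

One row per (nerve × hip shift × direction) condition: the model's region,
compared against the RoA estimated from that condition's simulated trials.
Specificity is uniformly high (the model rarely claims angles where
nothing moved); sensitivity is lower and more variable in the small
shifted-condition blocks, where a handful of trials and the 95 % coverage
rule make the estimated RoA fragile — the same qualitative picture as in
real campaigns of this design.

The same steps are available from a shell:

```sh
Rscript inst/cli/fescycle.R pattern  --direction cw --out out/
Rscript inst/cli/fescycle.R simulate --seed 42 --out out/
Rscript inst/cli/fescycle.R validate --trials out/trials.csv --out out/
```

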