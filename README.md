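# BrainHopf

Whole-brain coupled-oscillator modeling and dynamical subtyping for
resting-state fMRI cohorts, with the downstream clinical statistics of a
sham-controlled neurostimulation trial.

Treatment-resistant depression cohorts look homogeneous behaviorally yet
respond heterogeneously to stimulation. This package stratifies such a
cohort by the *dynamics* of pre-treatment resting-state activity: each of
68 cortical regions is a Stuart–Landau (Hopf) oscillator with an adaptive
angular frequency, coupled through a row-normalized structural connectome,

```
dz_j/dt = (A + i*w_j - |z_j|^2) z_j + G * sum_i C_ij (z_i - z_j) + beta*eta_j
dw_j/dt = w0_j - F*w_j + M * sum_i C_ij arg(z_i)
```

with global parameters A (bifurcation), G (coupling), F (frequency
feedback) and M (phase modulation), and noise SD beta = 0.02. The model is
fitted to empirical functional connectivity (band-passed 0.008–0.1 Hz,
Pearson FC, Fisher z) by grid search over 63,140 parameter combinations
combined with Monte-Carlo resampling of subjects (500 iterations at each
of the 30/50/70% thresholds, pooled to 1500). The pooled distribution of
selected parameter sets is bimodal; its two modes (DEP1/DEP2) define two
dynamical subtypes, each subject is assigned to the mode whose simulated
FC its own FC resembles more, and the clinical endpoints are analyzed with
balanced bootstrap, logistic and linear models with 1000-replicate
bootstrap CIs, and a nested ANOVA of subtype within treatment.

Because the trial's raw imaging is not redistributable, the package ships
a first-class synthetic-cohort generator (`generateCohort()`) producing a
consensus connectome, per-subject FC matrices from two ground-truth
parameter sets, and ordinal symptom tables (MADRS-S, BPRS-AFF, CAINS,
TMT) with injected subtype and treatment-by-subtype effects, so the whole
pipeline is testable offline. See the methods vignette
(`vignettes/whole-brain-subtyping.Rmd`) for the model, the design
decisions and their limits.

## Worked example

```r
library(BrainHopf)

spec <- syntheticCohortSpec(seed = 11)      # 42 subjects, 20 DEP1 / 22 DEP2
syn  <- generateCohort(spec)
bank <- simulateGrid(reducedGrid(), syn@connectome,
                     intrinsicFrequencies(syn@log$omega0),
                     simulationConfig(seed = spec$seed))
rec  <- monteCarloFit(bank, syn@fcs, itersPerThreshold = 50L, seed = 42)
sol  <- detectModes(rec, bank)
sol
#> SubtypeSolution (DEP1 = higher-metastability mode)
#>   DEP1: A=+0.020 G=0.035 F=0.40 M=0.46  (12 iterations)
#>   DEP2: A=-0.090 G=0.010 F=0.70 M=0.49  (138 iterations)

asg <- assignSubjects(syn@fcs, sol)
labelAccuracy(asg, truthReport(syn))
#> [1] 1
```

Both recovered modes are exactly the generator's ground-truth parameter
sets (the DEP1/DEP2 naming is a metastability convention and may swap
relative to the generator's labels; `labelAccuracy()` accounts for the
orientation), and all 42 subjects are assigned to their true subtype.
The treatment-by-subtype allocation control reproduces the textbook
worked value:

```r
unlist(chi2Test2x2(matrix(c(10, 10, 10, 12), 2, byrow = TRUE)))
#>  statistic         df          p
#> 0.08677686 1.00000000 0.76831541
```

`runPipeline(pipelineConfig(outputDir = "out"))` chains all stages —
connectome, cached grid bank, Monte-Carlo fit, mode detection,
assignment, dynamics metrics, clinical statistics — and writes a
manifest of seeds and content hashes sufficient to reproduce the run.

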