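# metarecon

Inverse reconstruction of biochemical Jacobians from the covariance of
replicate metabolite profiles, and differential-Jacobian ranking of
perturbed reaction elasticities between biological conditions — plus the
companion discriminant-metabolite statistics (Pareto scaling, PCA,
PLS-DA/OPLS-DA with VIP scores, permutation validation, fold changes)
used in targeted-metabolomics group comparisons.

## The idea

Around a metabolic steady state, replicate-to-replicate fluctuations of
metabolite concentrations behave like a stationary Ornstein–Uhlenbeck
process, so the measured covariance `C`, the system Jacobian `J`, and a
fluctuation (diffusion) matrix `F` are linked by the Lyapunov equation

    J C + C Jᵀ = −2 F.

`J` factors through the metabolic network as `J = N E`, with `N` the
stoichiometric matrix and `E` the elasticity matrix `∂r/∂C`, nonzero only
where a reaction's rate may depend on a metabolite (substrates and
declared modifiers). Given `C` estimated from replicates and a diagonal
model for `F`, the free elasticities solve a linear least-squares problem;
sampling `F` (1000 Monte-Carlo draws by default) yields an ensemble of
Jacobians summarized by entrywise median and interquartile range (IQR).
Comparing two conditions entrywise,

    score(i, j) = |median_B − median_A| / pooledIQR(i, j)²,

ranks the reaction elasticities most perturbed between conditions. The
package ships a fully synthetic ground-truth module — a D-serine-pathway
network with known Jacobian, OU simulation, and knockout-like
perturbations — so every stage is verifiable against truth; it is the
basis of the test suite.

## Worked example: detect a knockout-perturbed coupling

```r
library(metarecon)

net   <- serineNetwork()
net
#> MetabolicNetwork: 9 metabolites, 13 reactions
#>   free elasticities: 13 | Lyapunov equations: 45 (over-determined)
#>   metabolites: 3PG, NAD, 3PHP, NADH, Glu, PSer, KGA, LSer, DSer

# ground truth + a knockout-like condition: the NADH-KGA recycling
# elasticity (reaction GDH, metabolite KGA) damped to 30%
truth <- makeGroundTruth(net, seed = 1)
dat   <- generateTwoConditionDataset(truth, "GDH", "KGA", 0.3,
                                     nSamples = 1000, seed = 2)

ens <- lapply(c("control", "perturbed"), function(cond) {
  cv <- sampleCovariance(dat$profiles, condition = cond)
  ensembleInvert(inverseProblem(cv, net, defaultFluctuation(cv, seed = 3),
                                nDraws = 1000), cond)
})
dj <- differentialJacobian(ens[[1]], ens[[2]])
rankPerturbations(dj, topK = 5)
#>   rank          entry  row col     score signedDifference
#> 1    1  df_NAD/df_KGA  NAD KGA 834.77622      -0.05753786
#> 2    2 df_NADH/df_KGA NADH KGA 834.77622       0.05753786
#> 3    3  df_Glu/df_KGA  Glu KGA 834.77622      -0.05753786
#> 4    4  df_KGA/df_KGA  KGA KGA  53.88724       0.04529690
#> 5    5 df_3PHP/df_Glu 3PHP Glu  38.96564       0.02292774
```

The three top entries are exactly the Jacobian couplings that the GDH
elasticity feeds (rows NAD, NADH, Glu of the KGA column): the inferred
NADH–KGA coupling shifted by ~0.06 per unit KGA — an order of magnitude
above the next unperturbed entry once normalized by the ensemble IQR² —
flagging the planted lesion. `runMetarecon()` performs the same analysis
file-to-file (covariances, ensemble medians/IQRs, ranking, JSON manifest
with config hash and seed).

## Worked example: discriminant metabolites

```r
panel <- simulateIntensityPanel(seed = 1)  # 40 metabolites, 3 planted
S4Vectors::metadata(panel)$trueEffects     #   effects (2 SD), n = 6/6
#> [1] "M20" "M28" "M38"

ds <- discriminantStats(panel)             # OPLS-DA VIP + Welch t + log2 FC
subset(ds$table, selected)                 # rule: VIP > 1 and p < 0.05
#>    metabolite      vip      p_value   p_adj_bh log_fold_change selected
#> 20        M20 4.229880 0.0005400948 0.02160379      -0.5870127     TRUE
#> 28        M28 1.405704 0.0418519559 0.57100469      -0.2400023     TRUE
#> 38        M38 1.237257 0.0428253515 0.57100469      -0.3156276     TRUE

ps <- simulateIntensityPanel(nEffects = 8, effectSize = 3, seed = 2)
permutationValidate(ps, nPermutations = 200, seed = 4)
#> Permutation validation (plsda, n = 200)
#>   original R2Y = 0.997, Q2 = 0.942
#>   intercepts: R2 0.886, Q2 -0.628 -> valid
#>   permutation p-value (Q2) = 0.004975
```

All three planted metabolites — and nothing else — pass the selection
rule; on clearly separable data the original Q2 exceeds every one of 200
label-permuted refits.

See `vignettes/jacobian-reconstruction.Rmd` for the model, the design of
the synthetic generator, and all numerical choices.

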