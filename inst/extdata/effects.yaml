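# Default synthetic measurement model: baseline levels for every monitored
# parameter, planted stratum effects tying selected responses to covariates,
# and multiplicative season offsets.
#
# Baselines are realistic magnitudes for lightly polluted surface
# drinking-water sources (mg/L except pH). Noise is lognormal on the log
# scale by default ("sd" is the log-scale standard deviation), which keeps
# concentrations strictly positive; pH uses additive normal noise.
#
# A planted effect replaces a parameter's baseline mean with per-stratum
# means of the named covariate: categorical covariates use their labels,
# continuous covariates are split into as many quantile classes (Q1..Qk)
# as there are means. The stratified-variance share these effects induce
# (the expected geodetector q) is computable analytically from the means,
# the noise sd and the stratum sizes.
baseline:
  pH:     {mean: 7.8,    sd: 0.30, family: normal}
  DO:     {mean: 8.0,    sd: 0.12, family: lognormal}
  COD_Mn: {mean: 1.5,    sd: 0.25, family: lognormal}
  BOD_5:  {mean: 1.0,    sd: 0.30, family: lognormal}
  NH3_N:  {mean: 0.30,   sd: 0.40, family: lognormal}
  TP:     {mean: 0.05,   sd: 0.40, family: lognormal}
  TN:     {mean: 0.45,   sd: 0.30, family: lognormal}
  NO3_N:  {mean: 1.2,    sd: 0.40, family: lognormal}
  As:     {mean: 0.001,  sd: 0.40, family: lognormal}
  Hg:     {mean: 0.00002, sd: 0.40, family: lognormal}
  Cd:     {mean: 0.0002, sd: 0.50, family: lognormal}
  Cr6:    {mean: 0.004,  sd: 0.80, family: lognormal}   # high CV metal
  Pb:     {mean: 0.004,  sd: 0.80, family: lognormal}   # high CV metal
effects:
  - parameter: TN
    factor: Precipitation
    means: {Q1: 0.3, Q2: 0.45, Q3: 0.65}
    noise_sd: 0.30
    family: lognormal
  - parameter: TP
    factor: GDP
    means: {Q1: 0.03, Q2: 0.05, Q3: 0.08}
    noise_sd: 0.40
    family: lognormal
  - parameter: As
    factor: Precipitation
    means: {Q1: 0.0005, Q2: 0.001, Q3: 0.002}
    noise_sd: 0.40
    family: lognormal
  - parameter: Hg
    factor: GDP
    means: {Q1: 0.000015, Q2: 0.00002, Q3: 0.00003}
    noise_sd: 0.40
    family: lognormal
  - parameter: Cd
    factor: GDP
    means: {Q1: 0.0001, Q2: 0.0002, Q3: 0.0004}
    noise_sd: 0.50
    family: lognormal
  - parameter: Cr6
    factor: DEM
    means: {Q1: 0.002, Q2: 0.004, Q3: 0.010}
    noise_sd: 0.80
    family: lognormal
  - parameter: Pb
    factor: Precipitation
    means: {Q1: 0.002, Q2: 0.004, Q3: 0.009}
    noise_sd: 0.80
    family: lognormal
# Multiplicative season offsets applied to every parameter except pH
# (which gets them additively around 0 via (multiplier - 1)). Seasonal
# differences in observed water quality are slight, so the default is no
# offset.
season_multipliers: {wet: 1.0, dry: 1.0, normal: 1.0}
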