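# Default configuration for the logarithmic power-function universal
# eutrophication index:
#
#   EI_j = 10.77 * (ln x_j)^1.1826,   EI = sum_j W_j * EI_j
#
# x_j is a ratio-to-reference normalization: for harm-oriented indicators
# x_j = (C_j / C_j0) * x_max, for the benefit-oriented indicator DO the
# ratio is inverted before scaling; x_j is clamped to [1, x_max]. C_j0 is
# the "extremely poor" (severely eutrophic) anchor concentration, at which
# x_j = x_max and EI_j reaches its maximum. x_max is chosen so that
# EI_j spans 0-100 (10.77 * (ln x_max)^1.1826 = 100).
#
# The C_j0 anchors below are a NON-AUTHORITATIVE editable default chosen at
# severely eutrophic levels typical of Chinese freshwater assessment
# practice; substitute an audited table when one is available.
x_max: 721.9288
coef: 10.77
exponent: 1.1826
indicators: [DO, TP, TN, COD_Mn, BOD_5, NH3_N, NO3_N]
reference:
  DO:     {c0: 0.2,  orientation: benefit}   # mg/L, near-anoxic
  TP:     {c0: 2.0,  orientation: harm}
  TN:     {c0: 20.0, orientation: harm}
  COD_Mn: {c0: 60.0, orientation: harm}
  BOD_5:  {c0: 40.0, orientation: harm}
  NH3_N:  {c0: 12.0, orientation: harm}
  NO3_N:  {c0: 50.0, orientation: harm}
# Equal weights by default (W_j = 1/n); may be overridden with any positive
# weights, which are renormalized to sum to 1.
weights: equal
# Trophic grades: ordered lower bounds. An EI exactly on a boundary belongs
# to the higher (more eutrophic) grade. Only the grade-2/3 boundary (39.42)
# is anchored to the assessment convention in common use; other boundaries
# are NON-AUTHORITATIVE defaults.
grades:
  - {grade: 1, label: oligotrophic,       min: 0}
  - {grade: 2, label: mesotrophic,        min: 20}
  - {grade: 3, label: eutrophic,          min: 39.42}
  - {grade: 4, label: middle_eutrophic,   min: 55}
  - {grade: 5, label: heavy_eutrophic,    min: 70}
  - {grade: 6, label: severe_eutrophic,   min: 85}
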