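# Default WQI configuration.
#
# WQI = k * sum(C_i * P_i) / sum(P_i) over the eight parameters below.
# The normalization tables map raw concentrations (mg/L; pH unitless) to
# scores C_i on 0-100 by piecewise-linear interpolation between breakpoints;
# values beyond the extreme breakpoints are clamped. Score anchors follow
# the surface-water functional classes of GB3838-2002 (100 at the Class I
# limit stepping down to 0 well beyond Class V). These tables are a
# NON-AUTHORITATIVE editable default: published WQI scoring tables are not
# reproduced verbatim here and should be substituted when auditing against
# a specific scheme.
#
# k: 1.00 no significant pollution, 0.75 slight, 0.50 obvious, 0.25 high.
k: 1.00
weights:
  pH: 1
  DO: 4
  COD_Mn: 3
  BOD_5: 3
  NH3_N: 3
  TP: 4        # raised: high observed pollution level
  TN: 4        # raised: high observed pollution level
  NO3_N: 2
normalization:
  pH:
    orientation: two_sided
    conc:  [4.0, 6.0, 6.5, 7.0, 7.5, 8.0, 8.5, 9.0, 11.0]
    score: [0,   60,  80,  100, 100, 100, 80,  60,  0]
  DO:
    orientation: benefit
    conc:  [1.0, 2.0, 3.0, 5.0, 6.0, 7.5]
    score: [0,   20,  40,  60,  80,  100]
  COD_Mn:
    orientation: harm
    conc:  [2.0, 4.0, 6.0, 10.0, 15.0, 30.0]
    score: [100, 80,  60,  40,   20,   0]
  BOD_5:
    orientation: harm
    conc:  [3.0, 3.5, 4.0, 6.0, 10.0, 20.0]
    score: [100, 80,  60,  40,  20,   0]
  NH3_N:
    orientation: harm
    conc:  [0.15, 0.5, 1.0, 1.5, 2.0, 4.0]
    score: [100,  80,  60,  40,  20,  0]
  TP:
    orientation: harm
    conc:  [0.02, 0.1, 0.2, 0.3, 0.4, 0.8]
    score: [100,  80,  60,  40,  20,  0]
  TN:
    orientation: harm
    conc:  [0.2, 0.5, 1.0, 1.5, 2.0, 4.0]
    score: [100, 80,  60,  40,  20,  0]
  NO3_N:
    orientation: harm
    conc:  [1.0, 3.0, 10.0, 15.0, 20.0, 40.0]
    score: [100, 80,  60,   40,   20,   0]
# Ordered class scheme (upper bounds listed high to low). A WQI exactly on
# a boundary belongs to the better class.
classes:
  - {label: excellent, min: 90}
  - {label: good,      min: 70}
  - {label: medium,    min: 50}
  - {label: poor,      min: 25}
  - {label: very_poor, min: 0}
# Class III surface-water limits (GB3838-2002) used for exceedance summaries.
# orientation: max = concentration must not exceed; min = must not fall below.
class3_limits:
  DO:    {limit: 5.0,    orientation: min}
  COD_Mn: {limit: 6.0,   orientation: max}
  BOD_5: {limit: 4.0,    orientation: max}
  NH3_N: {limit: 1.0,    orientation: max}
  TP:    {limit: 0.2,    orientation: max}
  TN:    {limit: 1.0,    orientation: max}
  NO3_N: {limit: 10.0,   orientation: max}
  As:    {limit: 0.05,   orientation: max}
  Hg:    {limit: 0.0001, orientation: max}
  Cd:    {limit: 0.005,  orientation: max}
  Cr6:   {limit: 0.05,   orientation: max}
  Pb:    {limit: 0.05,   orientation: max}
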