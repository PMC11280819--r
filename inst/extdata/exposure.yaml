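# Oral-ingestion exposure model for the average daily dose
#
#   ADD = C * IR * EF * ED / (BW * AT)     [mg/(kg d)]
#
# with per-population (adult, child) distributions for the intake rate IR
# (L/d), exposure frequency EF (d/a), exposure duration ED (a) and body
# weight BW (kg). Distribution families/parameters follow standard USEPA
# oral-ingestion exposure-factor practice and are a NON-AUTHORITATIVE
# editable default.
#
# at_rule: "derived" computes the averaging time AT (d) as ED*365 for
# noncarcinogenic risk and lifetime_years*365 for carcinogenic risk (the
# standard USEPA convention); set an explicit AT spec per population to
# override.
at_rule: derived
lifetime_years: 70
populations:
  adult:
    IR: {family: normal, mean: 2.0, sd: 0.3, trunc_min: 0.5, trunc_max: 4.0}
    EF: {family: point, value: 365}
    ED: {family: point, value: 30}
    BW: {family: normal, mean: 65.0, sd: 8.0, trunc_min: 40, trunc_max: 110}
  child:
    IR: {family: normal, mean: 1.0, sd: 0.2, trunc_min: 0.3, trunc_max: 2.5}
    EF: {family: point, value: 365}
    ED: {family: point, value: 6}
    BW: {family: normal, mean: 20.0, sd: 3.0, trunc_min: 10, trunc_max: 40}
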