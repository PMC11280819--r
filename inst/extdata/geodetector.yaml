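# Geodetector settings.
#
# Continuous covariates are discretized before the factor detector runs;
# the method and class count are analysis choices (natural_breaks with 5
# classes is the dominant convention in geodetector applications).
# tolerance is the numeric slack used when classifying two-factor
# interactions into the five enhancement/weakening/independence categories.
method: natural_breaks
n_classes: 5
tolerance: 1.0e-9
# Which covariates are categorical (all others are treated as continuous
# and discretized).
categorical: [Soil_Type, Land_Use]
# Responses screened by default: nutrients plus the five heavy metals.
responses: [TN, TP, As, Hg, Cd, Cr6, Pb]
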