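# Oral toxicity references per metal: cancer slope factor SF ((mg/(kg d))^-1)
# for metals flagged carcinogenic, and reference dose RfD (mg/(kg d)) for
# all metals. Values are a NON-AUTHORITATIVE editable default drawn from
# standard USEPA oral-ingestion toxicity tables as commonly applied in
# drinking-water risk assessment; Hg carries no oral SF, so no carcinogenic
# risk is computed for Hg.
metals:
  As:  {SF: 1.5,    RfD: 0.0003,  carcinogenic: true}
  Hg:  {RfD: 0.0003, carcinogenic: false}
  Cd:  {SF: 6.1,    RfD: 0.0005,  carcinogenic: true}
  Cr6: {SF: 0.5,    RfD: 0.003,   carcinogenic: true}
  Pb:  {SF: 0.0085, RfD: 0.0014,  carcinogenic: true}
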