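# Overcapacity discipline aimed at dedicated high-seas vessels: those
# spending at least 95% of their fishing time beyond national jurisdiction
# lose their fuel and vessel-construction subsidies. Least-developed
# Members are exempt (special and differential treatment).
name: "High seas (>= 95% of time)"
disciplines:
  - category: OFOC
    predicate: high_seas_fraction_at_least
    threshold: 0.95
    removal_scope: listed_types
    listed_types: [fuel, vessel_construction]
    exempt_development: [LDC]
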