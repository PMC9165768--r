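# Reference scenario: complete removal of all subsidies with the potential
# to be capacity-enhancing, from every vessel. Upper bound of reform effects.
name: "Ambitious Reform"
disciplines:
  - category: OFOC
    predicate: always
    removal_scope: all_capacity_enhancing
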