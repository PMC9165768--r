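# Cap-and-tier example: developed Members capped at 3% of current
# (non-green-box) subsidy levels, developing and least-developed Members at
# 5%; management and research programmes are green-box (exempt from the cap
# base).
name: "Cap and tier (3% / 5% of current subsidies)"
disciplines: []
cap_rule:
  tier_by_status:
    developed: tier1
    developing: tier2
    LDC: tier2
  cap_basis: percent_of_current_subsidies
  cap_percent_by_tier:
    tier1: 3
    tier2: 5
  green_box_types: [management, research]
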