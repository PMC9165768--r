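{
  "_comment": "Unit multipliers: effective subsidies equal nominal subsidies. Replace with effort-effect normalizations (e.g. OECD-derived) to weight subsidy types differently.",
  "multiplier": {
    "fuel": 1.0,
    "vessel_construction": 1.0,
    "equipment": 1.0,
    "port_development": 1.0,
    "market_support": 1.0,
    "tax_exemption": 1.0,
    "buyback": 1.0,
    "management": 1.0,
    "research": 1.0
  }
}
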