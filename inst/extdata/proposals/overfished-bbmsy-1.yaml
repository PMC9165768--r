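# Prohibit subsidies to fishing on overfished stocks, defined as a
# B/B_MSY-like stock status below 1.
name: "Overfished (B/B_MSY < 1)"
disciplines:
  - category: overfished
    predicate: stock_status_below
    threshold: 1.0
    removal_scope: all_capacity_enhancing
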