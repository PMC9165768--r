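# The more conservative "negative effects" reading: prohibition only where
# the stock status falls below 0.8, proxying the need to demonstrate a
# negative subsidy effect.
name: "Overfished - negative effects (B/B_MSY < 0.8)"
disciplines:
  - category: overfished
    predicate: stock_status_below
    threshold: 0.8
    removal_scope: all_capacity_enhancing
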