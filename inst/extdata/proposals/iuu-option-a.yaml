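# Prohibit subsidies to vessels appearing on RFMO IUU lists; all
# capacity-enhancing subsidies are removed from listed vessels.
name: "IUU (Option A)"
disciplines:
  - category: IUU
    predicate: iuu_listed
    removal_scope: all_capacity_enhancing
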