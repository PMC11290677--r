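# Cost model for an Amazonian bat survey: mist-nets vs acoustic recorders.
# Fixed costs are one-off equipment purchases; variable costs accrue per
# surveyed site (one site sample = 2 nights x 4 researchers for mist-nets).
methods:
  mistnet:
    fixed: 520        # 18 nets x $20 + 20 poles x $8
    variable: 384     # 2 nights x $192 (4 researchers x $48)
    unit: "site (2 non-consecutive nights)"
  acoustic:
    fixed: 883.20     # 6 recorders x $60 + 6 cards x $67.20 + $120 hard disk
    variable: 1062    # $6 bags + $192 install/retrieve + $864 analysis (18 days)
    unit: "site (6 recorders, 2 nights)"
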