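# Decision-table band edges for the antenatal traffic-light triage engine.
# All bands are half-open, lower-inclusive: a value exactly at an edge takes
# the more severe color. Units are stated per key. Edit here, never in code.
bp:
  sbp_yellow: 140    # mmHg; SBP >= this is at least YELLOW
  sbp_red: 160       # mmHg; SBP >= this is RED (severe hypertension)
  dbp_yellow: 90     # mmHg
  dbp_red: 110       # mmHg
  si_yellow: 0.9     # shock index = HR / SBP, dimensionless
  si_red: 1.7
hb:
  red_below: 7.0          # g/dL; Hb < this is RED (severe anemia)
  referral_below: 10.0    # g/dL; YELLOW below this carries a referral item
  green_at_or_above: 11.0 # g/dL; Hb >= this is GREEN
ogtt:
  yellow_at_or_above: 140 # mg/dL, nonfasting 2-h capillary glucose (GDM)
  red_at_or_above: 200    # mg/dL (overt diabetes)
windows:
  enrol_min_days: 196     # 28+0 weeks gestation
  enrol_max_days: 258     # 36+6 weeks gestation
  pp_week1_start: 0       # days after delivery
  pp_week1_end: 7
  pp_week6_start: 36      # week-6 visit window, 42 +/- 6 days
  pp_week6_end: 48
resolution:               # measurement resolution, one step per mutation
  bp: 1                   # mmHg
  hr: 1                   # bpm
  hb: 0.1                 # g/dL
  glucose: 1              # mg/dL
  si: 0.01
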