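# Default CVD management decision table.
# Tiers: high (>=30% band, past CVD, or clinically high risk),
# intermediate (20-<30%), elevated (10-<20%), low (<10%).
# Conditionals are "any of" lists over the documented condition vocabulary.
tiers:
  high:
    interval_months: 3
    interval_range: [3, 6]
    referral: [always]
    medications:
      bp_lowering: [always]
      lipid_lowering: [always]
      antiplatelet: [always]
  intermediate:
    interval_months: 12
    referral: [always]
    medications:
      bp_lowering: [bp_140_90]
      lipid_lowering: [diabetes, sbp_160, tc_gt_200, ldl_gt_120]
      antiplatelet: [never]
  elevated:
    interval_months: 24
    referral: [diabetes, ifg, diabetes_history_and_sbp_160]
    medications:
      bp_lowering: [diabetes_and_bp_140_90, sbp_160]
      lipid_lowering: [diabetes, sbp_160]
      antiplatelet: [never]
  low:
    interval_months: 60
    referral: [diabetes, ifg, diabetes_history_and_sbp_160]
    medications:
      bp_lowering: [diabetes_and_bp_140_90, sbp_160]
      lipid_lowering: [diabetes, sbp_160]
      antiplatelet: [never]
thresholds:
  sbp_high: 160   # mmHg
  bp_sbp: 140     # mmHg
  bp_dbp: 90      # mmHg
  tc_gt: 200      # mg/dL
  ldl_gt: 120     # mg/dL
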