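{
  "demographics": {
    "patient_id": "DEMO-001",
    "location": "village A",
    "age": 33,
    "gender": "male"
  },
  "medical_history": {
    "past_mi_angina": false,
    "past_stroke": false,
    "past_pvd": false,
    "past_diabetes": true,
    "past_hypertension": null,
    "family_mi_angina": null,
    "family_stroke": null,
    "family_diabetes": null,
    "on_bp_lowering": null,
    "on_lipid_lowering": null,
    "on_antiplatelet": null
  },
  "risk_factors": {
    "smoker": true,
    "bp_readings": [
      [166, 95],
      [162, 91],
      [158, 87]
    ],
    "glucose_value": 180,
    "glucose_type": "fasting",
    "tc": 176,
    "hdl": 42,
    "height": 168,
    "weight": 70
  }
}
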