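{
  "y_max": 17,
  "factors": {
    "cofactor_mM": {
      "form": "bell_cofactor",
      "center": 50.372643036153,
      "center_shift": 29.1172985417103,
      "width": 15.2730364754187,
      "width_ratio": 0.7,
      "shape": 2,
      "floor": 0.12
    },
    "DTT_mM": {
      "form": "rise",
      "center": 4.41063882537865,
      "width": 0.5,
      "floor": 0.880359356241473
    },
    "RNaseInh_UmL": {
      "form": "rise",
      "center": 100,
      "width": 200,
      "floor": 0.995
    },
    "NTPs_mM": {
      "form": "rise",
      "center": 5.59379732790067,
      "width": 1.1445247443755,
      "floor": 0.778846996484894
    },
    "DNA_nM": {
      "form": "rise",
      "center": 40,
      "width": 20.1891825241111,
      "floor": 0.631948880700211
    },
    "PPase_UmL": {
      "form": "rise",
      "center": 1,
      "width": 4,
      "floor": 0.95
    },
    "spermidine_mM": {
      "form": "bell",
      "center": 1.47290494537052,
      "width": 5.91511228045411,
      "shape": 1.5,
      "floor": 0.4
    },
    "T7_UmL": {
      "form": "bell_log10",
      "center": 3.77815125038364,
      "width": 0.3,
      "shape": 1.5,
      "floor": 0.45
    },
    "temperature_C": {
      "form": "bell",
      "center": 40.5,
      "width": 8.75271254476715,
      "shape": 8,
      "floor": 0.3
    },
    "pH": {
      "form": "bell",
      "center": 6.5955511062505,
      "width": 1.66240831229857,
      "shape": 2,
      "floor": 0.25
    }
  },
  "kinetics": {
    "k": 0.0134119826036175,
    "t_peak": 120,
    "kinetic_scale": 0.877481557998993,
    "dsrna_onset": 115,
    "dsrna_asymptote": 0.05,
    "dsrna_tau": 30
  },
  "template": {
    "threshold_bp": 1500,
    "ref_bp": 5299,
    "size_factor_ref": 0.914003835061314,
    "decline_rate_ref": 0.00289243149939931
  },
  "noise_sd": 0.5,
  "rmse_anchors": 0.00271412118250247
}
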