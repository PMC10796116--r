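{
  "k_ref": {
    "ru": 1500,
    "tr": 40,
    "ri": 33,
    "p": 18000,
    "re": 5,
    "lb": 100,
    "gl": 400,
    "ld": 400
  },
  "eta": {
    "ru": 4800,
    "tr": 500,
    "ri": 7459,
    "p": 20000,
    "re": 1000,
    "lb": 2500,
    "gl": 3000,
    "ld": 3000
  },
  "q": {
    "ru": 0.31,
    "tr": 0.31,
    "ri": 0.38,
    "p": 0.28,
    "re": 0.31,
    "lb": 0.31,
    "gl": 0.31,
    "ld": 0.31
  },
  "E_a": {
    "ru": 0.85,
    "tr": 0.425,
    "ri": 0.85,
    "p": 0,
    "re": 0.85,
    "lb": 0.85,
    "gl": 0.85,
    "ld": 0.85
  },
  "temperature_independent": "p",
  "T_ref": 293.15,
  "k_ref_d": 0.4,
  "E_d": 2.5,
  "T_d": 304.15,
  "K_ic": 6000000,
  "K_in": 300000,
  "K_lb": 6000000,
  "K_ru": 10,
  "K_tr": 1,
  "K_p": 50,
  "eta_aac": 5,
  "eta_aa": 110,
  "eta_lic": 50,
  "n_guc": 6,
  "q_other": 0.315,
  "e_p": 1,
  "e_ru": 8,
  "e_ri": 4.5,
  "e_tr": 0.5,
  "e_lb": 5.5,
  "e_re": 1000,
  "e_gl": 5,
  "e_ld": 7,
  "f_dr": 0.25,
  "t_d": 720,
  "s_tr": 0.0001,
  "s_lm": 4e-07,
  "V_p": 2.4e-06,
  "V_li": 1.6e-08,
  "D_max": 12000000000,
  "w_ic": 30,
  "w_in": 17,
  "w_gu": 180,
  "density_pools": ["ru", "ri", "re", "lb", "gl", "ld"],
  "c_tag_min": 30000,
  "c_tag_max": 30000000,
  "M_min": 0.002,
  "M_max": 0.035,
  "T_min": 278.15,
  "T_max": 318.15,
  "membrane_saturation": true,
  "membrane_clamp": false,
  "phi_other": 0.5,
  "chl_per_ps": 140,
  "chl_mw": 893.5,
  "chl_include_damaged": true,
  "lipids_enabled": true,
  "damage_enabled": true,
  "track_carbon": true
}
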