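{
  "gm_like": {
    "water_t1": 2.0, "water_t2": 0.06,
    "amide_fs": 1.2e-3, "amide_ksw": 30, "amide_t2": 10e-3,
    "guanidyl_amine_fs": 0.8e-3, "guanidyl_amine_ksw": 500, "guanidyl_amine_t2": 2e-3,
    "hydroxyl_fs": 2.0e-3, "hydroxyl_ksw": 800, "hydroxyl_t2": 1e-3,
    "noe_m1p6_fs": 3.0e-3, "noe_m1p6_ksw": 20, "noe_m1p6_t2": 0.5e-3,
    "mt_fs": 60e-3, "mt_ksw": 25, "mt_t2": 0.05e-3,
    "noe_m3p5_fs": 25e-3, "noe_m3p5_ksw": 15, "noe_m3p5_t2": 4e-3
  },
  "wm_like": {
    "water_t1": 1.5, "water_t2": 0.04,
    "amide_fs": 1.0e-3, "amide_ksw": 25, "amide_t2": 8e-3,
    "guanidyl_amine_fs": 0.6e-3, "guanidyl_amine_ksw": 400, "guanidyl_amine_t2": 2e-3,
    "hydroxyl_fs": 1.5e-3, "hydroxyl_ksw": 700, "hydroxyl_t2": 1e-3,
    "noe_m1p6_fs": 4.0e-3, "noe_m1p6_ksw": 15, "noe_m1p6_t2": 0.6e-3,
    "mt_fs": 120e-3, "mt_ksw": 30, "mt_t2": 0.04e-3,
    "noe_m3p5_fs": 35e-3, "noe_m3p5_ksw": 12, "noe_m3p5_t2": 5e-3
  },
  "tumor_like": {
    "water_t1": 2.5, "water_t2": 0.08,
    "amide_fs": 2.5e-3, "amide_ksw": 60, "amide_t2": 12e-3,
    "guanidyl_amine_fs": 1.2e-3, "guanidyl_amine_ksw": 600, "guanidyl_amine_t2": 2.5e-3,
    "hydroxyl_fs": 3.0e-3, "hydroxyl_ksw": 1000, "hydroxyl_t2": 1.2e-3,
    "noe_m1p6_fs": 2.0e-3, "noe_m1p6_ksw": 25, "noe_m1p6_t2": 0.4e-3,
    "mt_fs": 30e-3, "mt_ksw": 20, "mt_t2": 0.06e-3,
    "noe_m3p5_fs": 15e-3, "noe_m3p5_ksw": 18, "noe_m3p5_t2": 3e-3
  }
}
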