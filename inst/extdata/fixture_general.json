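{
  "rates": {
    "u_A": {
      "alpha": 0.00917960221008381,
      "beta": 0.961179005613568,
      "gamma": 20.2488566656517
    },
    "v_A": {
      "alpha": 0.011259029330439,
      "beta": 0.865563916216643,
      "gamma": 30.3541738049582
    },
    "u_B": {
      "alpha": 0.00710622986710089,
      "beta": 0.7589278035397,
      "gamma": 8.24409719636605
    },
    "v_B": {
      "alpha": 0.00143301483164831,
      "beta": 1.43889638421628,
      "gamma": 15.4211945197976
    }
  },
  "kappa": {
    "uu_AA": 22.2564520387272,
    "uu_AB": 3.88291796485583,
    "uu_BA": 3.30188020886076,
    "uu_BB": 18.1371193706199,
    "uv_AA": 14.8776517939962,
    "uv_AB": 1.75476083301122,
    "uv_BA": 3.60595063379564,
    "uv_BB": 6.97149304723423,
    "vu_AA": 2.6093830605275,
    "vu_AB": 20.6207764831649,
    "vu_BA": 24.7829325889422,
    "vu_BB": 4.50958683668093,
    "vv_AA": 1.10860173259528,
    "vv_AB": 8.75246478830085,
    "vv_BA": 24.1400834776094,
    "vv_BB": 35.9072878911953
  },
  "D_u": 0.421582159833514,
  "D_v": 12.2557173380486,
  "seed": 20260930,
  "try": 3,
  "mode": "general",
  "d_used": 29.0707684188734
}
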