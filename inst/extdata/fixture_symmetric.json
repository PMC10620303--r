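{
  "rates": {
    "u_A": {
      "alpha": 0.00916811070348272,
      "beta": 0.713836014980299,
      "gamma": 8.61354472486633
    },
    "v_A": {
      "alpha": 0.00434051096567739,
      "beta": 0.862094044173702,
      "gamma": 18.5461240879966
    },
    "u_B": {
      "alpha": 0.00916811070348272,
      "beta": 0.713836014980299,
      "gamma": 8.61354472486633
    },
    "v_B": {
      "alpha": 0.00434051096567739,
      "beta": 0.862094044173702,
      "gamma": 18.5461240879966
    }
  },
  "kappa": {
    "uu_AA": 35.3558638574567,
    "uu_AB": 35.3558638574567,
    "uu_BA": 35.3558638574567,
    "uu_BB": 35.3558638574567,
    "uv_AA": 26.4447786438466,
    "uv_AB": 26.4447786438466,
    "uv_BA": 26.4447786438466,
    "uv_BB": 26.4447786438466,
    "vu_AA": 24.2023572859534,
    "vu_AB": 7.4062297045895,
    "vu_BA": 7.4062297045895,
    "vu_BB": 24.2023572859534,
    "vv_AA": 2.0751510487315,
    "vv_AB": 2.0751510487315,
    "vv_BA": 2.0751510487315,
    "vv_BB": 2.0751510487315
  },
  "D_u": 0.376397865261134,
  "D_v": 30.5667337687703,
  "seed": 20260930,
  "try": 15,
  "mode": "symmetric",
  "d_used": 81.2085736659636,
  "m": {
    "uu": 1,
    "uv": 1,
    "vu": 0.306012741531088,
    "vv": 1
  }
}
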