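profiles:
- name: symbia_lehr
  psf_fwhm_mm: 13.0
  sensitivity: 0.004
  acquisition_seconds: 3360.0
  noise: yes
  calibration_bias: 1.0
- name: infinia_me
  psf_fwhm_mm: 15.0
  sensitivity: 0.004
  acquisition_seconds: 3360.0
  noise: yes
  calibration_bias: 1.0
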