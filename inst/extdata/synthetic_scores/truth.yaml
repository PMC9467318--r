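generator: simulate_score_table
seed: 1.0
n_subjects: 58.0
params:
  trial_duration:
    betas:
    - 72.55
    - 22.97
    - -28.18
    - 14.2
    sd_subject: 17.22
    sd_resid: 20.9
    log: no
  mean_fixation_duration:
    betas:
    - 160.8
    - 3.4
    - 2.22
    - -1.9
    sd_subject: 19.85
    sd_resid: 6.2
    log: no
  mean_saccade_amplitude:
    betas:
    - 4.62
    - -0.18
    - -0.21
    - 0.45
    sd_subject: 0.5
    sd_resid: 0.344
    log: no
  n_fixations:
    betas:
    - 5.54
    - 0.25
    - -0.33
    - 0.3
    sd_subject: 0.26
    sd_resid: 0.206
    log: yes
  n_guiding:
    betas:
    - 53.73
    - -1.27
    - -2.58
    - 1.83
    sd_subject: 10.74
    sd_resid: 8.66
    log: no
  n_searching:
    betas:
    - 4.31
    - 0.34
    - -0.43
    - 0.26
    sd_subject: 0.3
    sd_resid: 0.302
    log: yes
  mean_eye_hand_span:
    betas:
    - 0.572
    - 0.05
    - -0.49
    - 0.27
    sd_subject: 0.23
    sd_resid: 0.247
    log: yes
  scanpath_length:
    betas:
    - 4.83
    - 0.31
    - -0.395
    - 0.35
    sd_subject: 0.27
    sd_resid: 0.247
    log: yes
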