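# The twelve exponential proportional-hazards non-inferiority scenarios
# (equal-arms alternative: rejection rate = power). Set hypothesis: null
# to place the research hazard at the margin instead (type-I error).
scenarios:
  - {id: 13, s3_control: 0.90, n_per_arm: 250,  hr_margin: 2.00, hypothesis: alternative}
  - {id: 14, s3_control: 0.90, n_per_arm: 450,  hr_margin: 1.75, hypothesis: alternative}
  - {id: 15, s3_control: 0.90, n_per_arm: 1000, hr_margin: 1.50, hypothesis: alternative}
  - {id: 16, s3_control: 0.90, n_per_arm: 3750, hr_margin: 1.25, hypothesis: alternative}
  - {id: 17, s3_control: 0.60, n_per_arm: 75,   hr_margin: 2.00, hypothesis: alternative}
  - {id: 18, s3_control: 0.60, n_per_arm: 125,  hr_margin: 1.75, hypothesis: alternative}
  - {id: 19, s3_control: 0.60, n_per_arm: 250,  hr_margin: 1.50, hypothesis: alternative}
  - {id: 20, s3_control: 0.60, n_per_arm: 1000, hr_margin: 1.25, hypothesis: alternative}
  - {id: 21, s3_control: 0.20, n_per_arm: 50,   hr_margin: 2.00, hypothesis: alternative}
  - {id: 22, s3_control: 0.20, n_per_arm: 75,   hr_margin: 1.75, hypothesis: alternative}
  - {id: 23, s3_control: 0.20, n_per_arm: 150,  hr_margin: 1.50, hypothesis: alternative}
  - {id: 24, s3_control: 0.20, n_per_arm: 450,  hr_margin: 1.25, hypothesis: alternative}
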