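# Template configuration for the synthetic risk-perception survey
# generator (see ?generator_config for every field and its default).
# Keys mirror the arguments of generator_config(); omit a key to keep
# the package default.

# respondents per smoking-status stratum (4 strata)
n_per_group: 410

# assessment objects to administer and framings to randomize over
objects: [CC, THS, ECIG, NRT, CESS]
framings: [P, G]

# latent normal person distribution, logits
person_sd:
  health: 2.9
  addiction: 3.4
# share of a respondent's latent variance common to all of their
# object-framing assessments (repeated-measures correlation)
person_cor: 0.5

# latent shift per smoking-status stratum, logits
group_offsets:
  CS_NIQ: -1.2
  CS_IQ: -0.4
  FS: 0.6
  NS: 1.0

# per-response "don't know" probability (published range 0.08-0.15)
dk_rate: 0.12

# logit shift applied when the object is not assessed first
carry_over:
  CC: 0.0
  THS: 0.0
  ECIG: 0.0
  NRT: 0.0
  CESS: 0.0

# auxiliary VAS measures
vas: true
vas_reliability: 0.6
vas_truth_cor: 0.8

seed: 20140201
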