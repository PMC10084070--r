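# Ungrooved (sham-operated contralateral) joint: homogeneous uptake laterally,
# depth-smooth partition field at the contralateral location mean.
name: control
groove_kind: none
cartilage_thickness_mm:
  mean: 0.501
  sd: 0.101
  min: 0.45
  max: 0.65
cavity_hu_t60: 1667
binp_bath_hu_offset: 0
bone_hu: 2500
noise_sd_hu: 40
partition_truth:
  lesion:        {mean: 42, sd: 9, between_sd: 4.5}
  away_3mm:      {mean: 42, sd: 9, between_sd: 4.5}
  contralateral: {mean: 42, sd: 9, between_sd: 4.5}
od_truth:
  lesion:        {mean: 1.1, sd: 0.2, between_sd: 0.1}
  away_3mm:      {mean: 1.1, sd: 0.2, between_sd: 0.1}
  contralateral: {mean: 1.1, sd: 0.2, between_sd: 0.1}
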