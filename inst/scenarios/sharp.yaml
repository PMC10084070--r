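# Sharp-groove arm: 400 um deep, 150 um wide blade groove; otherwise as the
# blunt scenario. Location means/SDs calibrated to the reference cohort table.
name: sharp
groove_kind: sharp
groove_depth_um: 400
groove_width_um: 150
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
  lesion:        {mean: 54, sd: 7,  between_sd: 3.5}
  away_3mm:      {mean: 43, sd: 5,  between_sd: 2.5}
  contralateral: {mean: 39, sd: 12, between_sd: 6.0}
od_truth:
  lesion:        {mean: 0.8, sd: 0.2, between_sd: 0.1}
  away_3mm:      {mean: 1.0, sd: 0.3, between_sd: 0.15}
  contralateral: {mean: 1.2, sd: 0.2, between_sd: 0.1}
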