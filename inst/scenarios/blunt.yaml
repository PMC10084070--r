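# Blunt-groove arm: a ~0.5 mm cartilage layer on bone carrying a 400 um deep,
# 500 um wide blunt groove, ioxaglate uptake elevated around the lesion, dual
# contrast agent (ioxaglate + BiNP) filling the joint cavity at 1667 HU at the
# 60-minute time point. Location means/SDs calibrated to the reference cohort
# table; `between_sd` is the joint-level component the generator injects.
name: blunt
groove_kind: blunt
groove_depth_um: 400
groove_width_um: 500
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
  lesion:        {mean: 66, sd: 18, between_sd: 9.0}
  away_3mm:      {mean: 45, sd: 11, between_sd: 5.5}
  contralateral: {mean: 42, sd: 9,  between_sd: 4.5}
od_truth:
  lesion:        {mean: 0.7, sd: 0.2, between_sd: 0.1}
  away_3mm:      {mean: 1.2, sd: 0.2, between_sd: 0.1}
  contralateral: {mean: 1.1, sd: 0.2, between_sd: 0.1}
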