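# Published rectum D_v values (Gy(RBE)) for five plans re-optimized with the
# translated LEM constraints and recalculated in both RBE languages.
patient_id,group,rectum_volume_cc,d_lem_20,d_mkm_20,d_lem_10,d_mkm_10,d_lem_5,d_mkm_5,d_lem_1,d_mkm_1
prostate_1,prostate,68.6,26.3,14.0,50.9,38.1,61.4,50.7,67.1,63.3
prostate_2,prostate,58.3,37.2,23.6,54.8,41.8,61.1,49.3,64.5,55.0
l_sac_1,l_sac,146.2,47.2,35.1,59.9,50.8,63.8,56.3,67.9,62.7
l_sac_2,l_sac,53.5,25.6,11.7,47.7,32.7,59.8,49.7,67.2,60.5
h_sac_1,h_sac,86.0,48.6,37.0,58.8,49.4,63.3,54.8,67.7,60.5
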