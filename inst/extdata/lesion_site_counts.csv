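site_group,n_whole_body,n_dynamic_fov
lymph_node,31,15
osseous,10,5
pulmonary,16,13
mesenterial_abdominal,12,7
soft_tissue,29,15
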