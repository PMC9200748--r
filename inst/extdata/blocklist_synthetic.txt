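Nuclei_Colocalization_AGP_costes
Cells_Colocalization_DNA_manders
Cytoplasm_Granularity_Mito_g14
Cells_Texture_ER_saturation
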