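network,region,hemisphere,column_id,base_prop
FPN,superior frontal gyrus (prefrontal cortex),left,superior_frontal_gyrus_prefrontal_left,0.0200
FPN,superior frontal gyrus (prefrontal cortex),right,superior_frontal_gyrus_prefrontal_right,0.0200
FPN,middle frontal gyrus (posterior segment),left,middle_frontal_gyrus_posterior_left,0.0060
FPN,middle frontal gyrus (posterior segment),right,middle_frontal_gyrus_posterior_right,0.0060
FPN,middle frontal gyrus (dorsal prefrontal cortex),left,middle_frontal_gyrus_dorsal_prefrontal_left,0.0120
FPN,middle frontal gyrus (dorsal prefrontal cortex),right,middle_frontal_gyrus_dorsal_prefrontal_right,0.0120
FPN,inferior frontal gyrus (pars opercularis),left,inferior_frontal_gyrus_pars_opercularis_left,0.0040
FPN,inferior frontal gyrus (pars opercularis),right,inferior_frontal_gyrus_pars_opercularis_right,0.0040
FPN,inferior frontal gyrus (pars orbitalis),left,inferior_frontal_gyrus_pars_orbitalis_left,0.0030
FPN,inferior frontal gyrus (pars orbitalis),right,inferior_frontal_gyrus_pars_orbitalis_right,0.0030
FPN,precentral gyrus,left,precentral_gyrus_left,0.0120
FPN,precentral gyrus,right,precentral_gyrus_right,0.0120
FPN,supramarginal gyrus,left,supramarginal_gyrus_left,0.0080
FPN,supramarginal gyrus,right,supramarginal_gyrus_right,0.0080
FPN,angular gyrus,left,angular_gyrus_left,0.0090
FPN,angular gyrus,right,angular_gyrus_right,0.0090
FPN,precuneus,left,precuneus_left,0.0100
FPN,precuneus,right,precuneus_right,0.0100
FPN,inferior temporal gyrus,left,inferior_temporal_gyrus_left,0.0100
FPN,inferior temporal gyrus,right,inferior_temporal_gyrus_right,0.0100
FPN,middle occipital gyrus,left,middle_occipital_gyrus_left,0.0120
FPN,middle occipital gyrus,right,middle_occipital_gyrus_right,0.0120
DMN,posterior cingulate cortex,left,posterior_cingulate_cortex_left,0.0040
DMN,posterior cingulate cortex,right,posterior_cingulate_cortex_right,0.0040
DMN,rostral anterior cingulate cortex,left,rostral_anterior_cingulate_cortex_left,0.0030
DMN,rostral anterior cingulate cortex,right,rostral_anterior_cingulate_cortex_right,0.0030
DMN,precuneus,left,precuneus_left,0.0100
DMN,precuneus,right,precuneus_right,0.0100
DMN,cuneus,left,cuneus_left,0.0050
DMN,cuneus,right,cuneus_right,0.0050
DMN,middle temporal gyrus,left,middle_temporal_gyrus_left,0.0120
DMN,middle temporal gyrus,right,middle_temporal_gyrus_right,0.0120
DMN,angular gyrus,left,angular_gyrus_left,0.0090
DMN,angular gyrus,right,angular_gyrus_right,0.0090
DMN,gyrus rectus,left,gyrus_rectus_left,0.0030
DMN,gyrus rectus,right,gyrus_rectus_right,0.0030
DMN,middle frontal orbital gyrus,left,middle_frontal_orbital_gyrus_left,0.0040
DMN,middle frontal orbital gyrus,right,middle_frontal_orbital_gyrus_right,0.0040
DMN,superior frontal gyrus (prefrontal cortex),left,superior_frontal_gyrus_prefrontal_left,0.0200
DMN,superior frontal gyrus (prefrontal cortex),right,superior_frontal_gyrus_prefrontal_right,0.0200
DMN,superior frontal gyrus (pole),left,superior_frontal_gyrus_pole_left,0.0040
DMN,superior frontal gyrus (pole),right,superior_frontal_gyrus_pole_right,0.0040
DMN,amygdala,left,amygdala_left,0.0016
DMN,amygdala,right,amygdala_right,0.0016
DMN,parahippocampal gyrus,left,parahippocampal_gyrus_left,0.0040
DMN,parahippocampal gyrus,right,parahippocampal_gyrus_right,0.0040
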