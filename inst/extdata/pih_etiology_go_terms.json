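{
  "endothelial_cell_activation_and_injury": [
    "GO:0007596",
    "GO:0030168",
    "GO:0002576",
    "GO:0030195",
    "GO:0010544",
    "GO:0007597",
    "GO:0072012"
  ],
  "placental_or_trophoblast_cell_ischemia": [
    "GO:0045429",
    "GO:0008217",
    "GO:0043066",
    "GO:0001890",
    "GO:0010595",
    "GO:0042311",
    "GO:0007263",
    "GO:0001974",
    "GO:0001525",
    "GO:0051000",
    "GO:0035924",
    "GO:0048010",
    "GO:0045766"
  ],
  "hypoxia_and_oxidative_stress": [
    "GO:2000379",
    "GO:0071456",
    "GO:0001666",
    "GO:0034097",
    "GO:0019221"
  ],
  "maternal_fetal_immune_tolerance_disorders": [
    "GO:0071356",
    "GO:0001819",
    "GO:1902042",
    "GO:0071347",
    "GO:0030217",
    "GO:0050852",
    "GO:0032757"
  ]
}
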