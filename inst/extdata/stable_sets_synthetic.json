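{
  "_comment": "Synthetic worked example of three seasons' stable vegetation-index sets, reconstructed to exercise the cross-year set partition: 12/12/28 indices per season, union 31, 16 shared by at least two seasons, 5 common to all three. Region members not uniquely determined by those counts were filled with plausible indices from the registry.",
  "2020": ["EVI", "LCI", "MCARI2", "MSAVI", "MTCI", "OSAVI", "RDVI",
           "RIgreen", "RIrededge", "SAVI", "mND705", "mSR705"],
  "2021": ["CIgreen", "CVI", "LCI", "MTCI", "PBI", "RIgreen", "RIrededge",
           "SR705", "TGI", "mND705", "mSR705", "reNDVI"],
  "2022": ["ARI", "CIgreen", "CRIrededge", "DATT", "EVI", "GNDVI", "mARI",
           "LCI", "MCARI", "MCARI2", "MSAVI", "MTCI", "NDVI", "OSAVI",
           "PBI", "RDVI", "RIrededge", "RVI", "SAVI", "SR445", "SR705",
           "TCARI_OSAVI", "TVI", "VARI", "WDRVI", "mND705", "mSR705",
           "reNDVI"]
}
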