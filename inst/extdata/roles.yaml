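# Example structure-name to role mapping for DICOM RT Structure Set
# ingestion. Keys are canonical roles; values are case-insensitive regular
# expressions tried in order against the delineated structure names.
ITV: "^itv"
PTV: "^ptv"
LUNG_IPSI: "lung.*(ipsi|links|left|l)|(ipsi).*lung"
LUNG_CONTRA: "lung.*(contra|rechts|right|r)|(contra).*lung"
CHEST_WALL: "chest|thorax.*wall|rib"
SPINAL_CANAL: "spinal|myelon|cord|canal"
ESOPHAGUS: "eso|oeso"
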