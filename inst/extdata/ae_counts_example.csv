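regimen,category,n_patients,grade1,grade2,grade3,grade4
FLOT,hematological,20,0,4,8,8
FLO_mFOLFOX,hematological,3,2,1,0,0
FOLFIRINOX,hematological,5,0,0,4,1
FLOT,anemia,20,10,4,1,0
FLO_mFOLFOX,anemia,3,1,1,0,0
FOLFIRINOX,anemia,5,3,0,2,0
FLOT,thrombocytopenia,20,7,0,0,0
FLO_mFOLFOX,thrombocytopenia,3,1,1,0,0
FOLFIRINOX,thrombocytopenia,5,1,0,1,0
FLOT,leukocytopenia,20,0,10,5,1
FLO_mFOLFOX,leukocytopenia,3,2,1,0,0
FOLFIRINOX,leukocytopenia,5,0,3,1,0
FLOT,neutropenia,20,1,2,7,8
FLO_mFOLFOX,neutropenia,3,1,0,0,0
FOLFIRINOX,neutropenia,5,0,0,3,1
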