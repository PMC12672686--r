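variable,category,MGUS,SMM,NDMM,RRMM
Gender,Male,3,7,10,12
Gender,Female,8,13,9,6
Race,American Indian or Alaskan Native,0,0,0,1
Race,Asian,0,0,0,1
Race,Black or African American,0,2,4,2
Race,Native Hawaiian or Other Pacific Islander,0,1,0,0
Race,Other,0,1,0,2
Race,White or Caucasian,11,16,15,12
Ethnicity,Hispanic or Latino,0,0,5,5
Ethnicity,Not Hispanic or Latino,11,20,13,13
Ethnicity,Patient Refused,0,0,1,0
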