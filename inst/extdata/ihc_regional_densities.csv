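group,region,iba1,tspo,ratio
SVD,caudate,4.60,0.73,17
SVD,internal_capsule,10.21,0.72,8
SVD,pallidus,7.62,2.43,56
SVD,putamen,4.15,0.38,11
HC,internal_capsule,3.66,1.24,34
HC,pallidus,2.41,1.70,72
HC,putamen,1.68,1.35,83
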