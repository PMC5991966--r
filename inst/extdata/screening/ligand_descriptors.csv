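ligand,donors,acceptors,mass,logp,marked_compliant
ZINC29590259,4,13,696.129,5.73,FALSE
ZINC29590263,4,13,696.129,5.73,FALSE
ZINC18141294,1,9,453.482,4.43,FALSE
ZINC01690699,4,8,548.606,6.89,FALSE
ZINC04773602,2,2,358.529,6.03,FALSE
ZINC29590257,4,13,696.129,5.73,FALSE
ZINC13099051,1,3,447.644,5.66,FALSE
ZINC01639634,4,9,488.507,5.61,FALSE
ZINC18057104,3,9,506.566,5.00,FALSE
ZINC04783229,2,6,476.580,6.47,FALSE
ZINC01694053,6,8,488.979,2.06,TRUE
ZINC01572309,4,8,474.571,5.84,FALSE
ZINC01707130,3,8,299.290,-0.28,TRUE
ZINC01568793,0,6,484.596,4.28,TRUE
ZINC13152284,2,4,392.458,6.51,FALSE
ZINC00084617,1,6,333.323,2.71,TRUE
ZINC13208966,2,2,275.351,3.91,TRUE
ZINC04720972,3,5,382.419,6.01,FALSE
ZINC11677172,2,6,496.575,3.78,TRUE
ZINC00393674,2,5,314.348,3.11,TRUE
ZINC01701460,0,2,367.279,7.26,FALSE
ZINC15952559,3,5,271.251,3.07,TRUE
ZINC11677178,2,6,496.575,3.78,TRUE
ZINC12671898,0,4,412.570,4.70,TRUE
ZINC17353914,2,5,472.629,4.96,TRUE
ZINC01573829,0,3,353.450,5.98,FALSE
ZINC01577889,2,4,392.458,5.41,FALSE
ZINC29590275,1,3,447.003,6.38,FALSE
ZINC01726776,0,5,398.853,5.98,FALSE
ZINC17465979,6,10,546.528,5.26,FALSE
ZINC05462670,6,10,546.528,5.26,FALSE
ZINC05462674,6,10,546.528,5.26,FALSE
ZINC12672242,2,3,410.524,5.61,FALSE
ZINC17465983,6,10,546.528,5.26,FALSE
ZINC01668429,6,11,499.531,1.34,FALSE
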