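ligand,target,site,energy,n_interactions
ZINC29590259,4LX0_C,site1,-8.9,7
ZINC29590259,5C46_F,site1,-8.2,10
ZINC29590259,1OIV_A,site1,-8.5,5
ZINC29590259,4OJK_A,site2,-8.4,4
ZINC29590263,4LX0_C,site1,-9.0,6
ZINC29590263,4OJK_A,site2,-8.3,4
ZINC18141294,1OIV_A,site1,-8.9,5
ZINC18141294,4OJK_A,site2,-8.0,4
ZINC01690699,4LX0_C,site1,-9.9,2
ZINC01690699,1OIV_A,site1,-8.6,6
ZINC01690699,4C4P_A,site2,-8.6,5
ZINC01690699,5C46_F,site1,-8.7,3
ZINC01690699,4UJ5_B,site2,-8.9,2
ZINC01690699,1YZK_A,site2,-8.6,3
ZINC01690699,5JCZ_D,site1,-8.3,4
ZINC04773602,1YZK_A,site2,-8.0,10
ZINC29590257,5C46_F,site1,-8.2,9
ZINC29590257,4LX0_C,site1,-8.7,4
ZINC29590257,4OJK_A,site2,-8.4,4
ZINC13099051,4LX0_C,site1,-9.4,5
ZINC13099051,1OIV_A,site1,-8.6,3
ZINC01639634,4LX0_C,site1,-8.6,5
ZINC18057104,1OIV_A,site1,-9.1,6
ZINC18057104,4LX0_C,site1,-8.8,4
ZINC18057104,4UJ5_B,site2,-8.3,2
ZINC04783229,4LX0_C,site1,-9.6,3
ZINC04783229,4OJK_A,site2,-9.0,1
ZINC04783229,4UJ5_B,site1,-8.5,2
ZINC04783229,4C4P_A,site2,-8.4,2
ZINC01694053,4LX0_C,site1,-8.6,6
ZINC01694053,4C4P_A,site2,-8.3,4
ZINC01572309,1YZK_A,site2,-8.8,4
ZINC01572309,4C4P_A,site2,-8.3,5
ZINC01572309,4OJK_A,site2,-8.4,5
ZINC01572309,1OIV_A,site1,-8.6,3
ZINC01707130,4LX0_C,site1,-8.5,4
ZINC01568793,4LX0_C,site1,-9.0,5
ZINC01568793,5JCZ_D,site1,-8.6,4
ZINC01568793,1OIV_A,site1,-8.5,6
ZINC01568793,4C4P_A,site2,-8.3,3
ZINC01568793,4UJ5_B,site2,-8.0,3
ZINC13152284,4LX0_C,site1,-9.2,3
ZINC13152284,1OIV_A,site1,-9.1,1
ZINC13152284,4UJ5_B,site2,-8.3,1
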