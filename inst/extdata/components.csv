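name,molar_mass,density,molar_volume,groups
thymol,150.22,0.965,,C6H3:1;OH:1;CH3:3;CH:1
menthol,156.27,0.890,,CH3:3;CH2:3;CH:4;ring:1;OH:1
tetrabutylammonium bromide,322.37,1.039,,CH3:4;CH2:12;N:1;Br:1
betaine,117.15,1.330,,CH3:3;CH2:1;N:1;COO:1
choline chloride,139.62,1.100,,CH3:3;CH2:2;N:1;OH:1;Cl:1
tannic acid,1701.20,2.120,,C6H2:10;OH:25;COO:10;CH:5;CH2:1;ring:1;O:1
diglycolic acid,134.09,1.424,,COOH:2;CH2:2;O:1
octanoic acid,144.21,0.910,,CH3:1;CH2:6;COOH:1
decanoic acid,172.26,0.8886,,CH3:1;CH2:8;COOH:1
dodecanoic acid,200.32,0.8679,,CH3:1;CH2:10;COOH:1
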