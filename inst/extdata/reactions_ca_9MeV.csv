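# Single-energy (9 MeV deuteron) cross-sections for every channel open on
# the calcium isotopes, in millibarn.
reaction_id,target_isotope,product,energy_MeV,sigma_mb
"Ca-40(d,p)Ca-41",Ca-40,Ca-41,9,369.00
"Ca-40(d,n)Sc-41",Ca-40,Sc-41,9,41.68
"Ca-40(d,a)K-38",Ca-40,K-38,9,30.70
"Ca-42(d,p)Ca-43",Ca-42,Ca-43,9,266.74
"Ca-42(d,n)Sc-43",Ca-42,Sc-43,9,104.73
"Ca-42(d,a)K-40",Ca-42,K-40,9,60.08
"Ca-43(d,p)Ca-44",Ca-43,Ca-44,9,105.31
"Ca-43(d,n)Sc-44",Ca-43,Sc-44,9,128.42
"Ca-43(d,2n)Sc-43",Ca-43,Sc-43,9,228.04
"Ca-43(d,a)K-41",Ca-43,K-41,9,65.85
"Ca-44(d,p)Ca-45",Ca-44,Ca-45,9,84.75
"Ca-44(d,n)Sc-45",Ca-44,Sc-45,9,262.34
"Ca-44(d,2n)Sc-44",Ca-44,Sc-44,9,264.24
"Ca-44(d,a)K-42",Ca-44,K-42,9,24.45
"Ca-46(d,p)Ca-47",Ca-46,Ca-47,9,215.50
"Ca-46(d,n)Sc-47",Ca-46,Sc-47,9,155.62
"Ca-46(d,2n)Sc-46",Ca-46,Sc-46,9,620.39
"Ca-46(d,a)K-44",Ca-46,K-44,9,7.11
"Ca-48(d,p)Ca-49",Ca-48,Ca-49,9,40.09
"Ca-48(d,n)Sc-49",Ca-48,Sc-49,9,93.64
"Ca-48(d,2n)Sc-48",Ca-48,Sc-48,9,1116.59
"Ca-48(d,a)K-46",Ca-48,K-46,9,2.12
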