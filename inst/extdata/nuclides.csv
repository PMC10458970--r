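# Nuclide library: decay constants and principal emission lines.
# lines = semicolon-separated keV:intensity pairs (photons per decay).
symbol,mass_number,molar_mass_g_mol,half_life_s,stable,lines
Sc-41,41,40.9692,0.5963,false,511:1.998
Sc-43,43,42.9612,14007.6,false,372.8:0.225;511:1.762
Sc-44,44,43.9594,14292,false,1157.02:0.999;511:1.887
Sc-45,45,44.9559,,true,
Sc-46,46,45.9552,7239456,false,889.28:0.9998;1120.55:0.9999
Sc-47,47,46.9524,289370.88,false,159.381:0.683
Sc-48,48,47.9522,157212,false,983.53:1.001;1037.52:0.976;1312.12:1.001
Sc-49,49,48.9500,3430.8,false,1761.96:0.0005
Ca-41,41,40.9623,3136826000000,false,
Ca-43,43,42.9588,,true,
Ca-44,44,43.9555,,true,
Ca-45,45,44.9562,14049504,false,
Ca-47,47,46.9545,392256,false,1297.09:0.671
Ca-49,49,48.9557,523.2,false,3084.4:0.921
K-38,38,37.9691,0.9244,false,511:2.0;2167.5:0.9985
K-40,40,39.9640,39446990000000000,false,1460.82:0.1067
K-41,41,40.9618,,true,
K-42,42,41.9624,44496,false,1524.6:0.1808
K-44,44,43.9616,1327.8,false,1157.0:0.58
K-46,46,45.9620,105,false,1346.7:0.538
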