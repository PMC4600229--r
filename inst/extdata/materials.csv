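name,scattering_length,molecular_volume,magnetic_sld,note
si,4.1491,20.0,0,crystalline silicon substrate (literature default)
sio2,15.7551,45.4,0,native oxide; amorphous SiO2 (literature default)
permalloy,10.13,11.11,2.1,Ni80Fe20 magnetic reference layer; magnetised in plane (literature default)
au,7.63,16.96,0,gold film (literature default)
thiolipid_chains,-32.44,825,0,hydrogenated omega-thiolipid alkyl chains per C30H62 unit (literature default)
pc_head,60.07,319,0,phosphatidylcholine head group C10H18NO8P (literature default)
dppc_tails_h,-32.44,825,0,hydrogenated DPPC tail pair C30H62 (literature default)
dppc_tails_d,612.98,825,0,chain-deuterated DPPC tail pair C30D62 (literature default)
lps_tails,-47.67,2430,0,lipid A acyl chains ~C84H162 per LPS (literature default)
lps_core,315.1,1700,0,Ra-LPS core oligosaccharide ~10 anhydrosugar residues (literature default)
lactoferrin,19000,95000,0,whole-protein average; labile H not exchanged (literature default)
lysozyme,3440,17200,0,whole-protein average; labile H not exchanged (literature default)
h2o,-1.6743,30.0,0,light water
d2o,19.1453,30.0,0,heavy water
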