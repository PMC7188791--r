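name,solubility_ref,T_ref,vant_hoff_K,setschenow,n_atoms
O2,1.3e-3,298.15,1700,0.0534,0
NO,1.9e-3,298.15,1600,0.0534,1
N2O,2.5e-2,298.15,2600,0.0534,2
N2,6.4e-4,298.15,1600,0.0534,2
He,3.8e-4,298.15,230,0.0534,0
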