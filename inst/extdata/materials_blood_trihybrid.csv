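name,rho,k,cp,beta_T,shape
blood,1053,0.492,3594,0.8,base_fluid
Fe3O4,5200,6,670,1.3,spherical
Zn,7140,116,389,3.5,cylindrical
Au,19300,318,129,1.41,platelet
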