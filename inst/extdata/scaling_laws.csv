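task,parameter,source,coefficient,exponent,units
swing,t_sm,literature,31,0.21,ms
swing,limb_mass,literature,5.8e-2,1.00,kg
swing,inertia,literature,2.52e-4,1.75,kg.m^2
swing,l_com,literature,5.6e-2,0.36,m
swing,tau_iso,literature,0.54,1.19,N.m
swing,available_time,literature,147.9,0.17,ms
posture,t_sm,literature,31,0.21,ms
posture,inertia,literature,2.64e-2,1.74,kg.m^2
posture,l_com,literature,1.62e-1,0.37,m
posture,tau_iso,literature,3.41,1.21,N.m
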