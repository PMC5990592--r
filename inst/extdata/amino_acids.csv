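name,code,formula,n_nitrogen,rt_start_min,rt_end_min,quantify_jointly_with,excluded_conditions
Alanine,A,C3H7NO2,1,1.0,1.4,,
Arginine,R,C6H14N4O2,4,1.5,1.9,,
Asparagine,N,C4H8N2O3,2,2.0,2.4,,
Aspartic acid,D,C4H7NO4,1,2.5,2.9,,
Glutamic acid,E,C5H9NO4,1,3.0,3.4,,dark_sucrose
Glutamine,Q,C5H10N2O3,2,3.5,3.9,,
Glycine,G,C2H5NO2,1,4.0,4.4,,
Histidine,H,C6H9N3O2,3,4.5,4.9,,"light_sucrose,light_no_sucrose,dark_sucrose"
Isoleucine/Leucine,I/L,C6H13NO2,1,5.0,5.4,,
Lysine,K,C6H14N2O2,2,5.5,5.9,,
Phenylalanine,F,C9H11NO2,1,6.0,6.4,,
Proline,P,C5H9NO2,1,6.5,6.9,,
Serine,S,C3H7NO3,1,7.0,7.4,,
Threonine,T,C4H9NO3,1,7.5,7.9,,
Tryptophan,W,C11H12N2O2,2,8.0,8.4,,
Tyrosine,Y,C9H11NO3,1,8.5,8.9,,"light_no_sucrose,dark_sucrose"
Valine,V,C5H11NO2,1,9.0,9.4,,"light_no_sucrose,dark_sucrose"
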