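name,group,lag_result,pka_acid,pka_base,delta_pka_reported,prediction_reported
Pyrocatechol,phenol,new_phase,9.64,,-0.24,cocrystal
Hydroquinone,phenol,new_phase,9.98,,-0.58,cocrystal
Resorcinol,phenol,new_phase,9.57,,-0.17,cocrystal
Pyrogallol,phenol,new_phase,9.1,,0.3,continuum
Methyl-hydroquinone,phenol,amorphous,10.1,,-0.7,cocrystal
Benzoic acid,acid,amorphous,4.08,,5.32,salt
Succinic acid,acid,new_phase,3.86,,5.54,salt
Pyroglutamic acid,acid,new_phase,3.61,,5.79,salt
4-hydroxybenzoic acid,acid,physical_mixture,4.38,,5.02,salt
Pyrrole-2-carboxylic acid,acid,physical_mixture,3.62,,5.78,salt
Oxamic acid,acid,physical_mixture,2.48,,6.92,salt
Saccharin,acid,physical_mixture,1.94,,7.46,salt
Acetamide,amide,physical_mixture,16.75,,-7.35,cocrystal
Glycolamide,amide,physical_mixture,13.65,,-4.25,cocrystal
Benzamide,amide,physical_mixture,14.56,,-5.16,cocrystal
Nicotinamide,amide,physical_mixture,13.39,,-3.99,cocrystal
Isonicotinamide,amide,physical_mixture,13.71,,-4.31,cocrystal
Urea,amide,physical_mixture,16.3,,-6.9,cocrystal
Piperazine,base,physical_mixture,,9.26,,not_applicable
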