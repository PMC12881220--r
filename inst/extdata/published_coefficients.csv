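rate_kind,metabolic_group,brose_intercept,brose_ci_lo,brose_ci_hi,updated_intercept,updated_cri_lo,updated_cri_hi,brose_coefficient,updated_coefficient,yodzis_innes_coefficient
metabolism,ecto_invertebrate,17.17,16.97,17.44,16.65,14.78,18.45,0.314,0.13,0.5
metabolism,ecto_vertebrate,18.18,18.01,18.29,17.4,16.46,18.28,0.88,0.274,2.3
metabolism,endo_vertebrate,19.5,19.37,19.78,19.53,18.93,20.13,3.22,2.27,54.9
production,producer,10.15,10.12,10.18,10.31,9.27,11.34,1,1,0.4
production,ecto_invertebrate,11.34,10.83,11.86,11.78,10.73,12.99,NA,NA,9.2
production,ecto_vertebrate,10.85,10.67,11.03,10.78,9.37,12.21,NA,NA,6.6
production,endo_vertebrate,10.29,10.25,10.33,9.83,9.16,10.51,NA,NA,34.3
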