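stock,value,units,source
healthy_mil,2050000,persons,synthetic reconstruction (total selected force 2000)
ill_undiag_mil,40000,persons,synthetic reconstruction (calibrated)
ill_diag_mil,7000,persons,synthetic reconstruction (calibrated)
healthy_vet,2830000,persons,synthetic reconstruction (VA-relevant veteran population 2000)
ill_undiag_vet,1180000,persons,synthetic reconstruction (calibrated)
ill_diag_vet_recent,0,persons,definition (Iraq/Afghanistan-era cohort empty in 2000)
ill_diag_vet_pre2000,100000,persons,synthetic reconstruction (pre-2000 diagnosed veterans)
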