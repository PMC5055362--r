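name,value,units,source
frac_recruit_ptsd_history,0.005,dimensionless,synthetic placeholder (recruits with pre-enlistment PTSD history)
trauma_exposure_rate,3.4,1/year,package calibration to historical series
p_ptsd_given_trauma,0.17,dimensionless,main text (base likelihood of 17%)
frac_reveal_mil,0.043,1/year,main text (fractional rate of revealing symptoms 0.043/year)
frac_treat_mil,0.125,1/year,main text (fractional treatment rate 0.125/year)
frac_reveal_vet,0.18,1/year,package calibration to historical series
frac_treat_vet,0.067,1/year,package calibration to historical series
separation_rate_healthy,0.10,1/year,synthetic placeholder (demographic plausibility)
separation_rate_undiag,0.13,1/year,package calibration to historical series
discharge_rate_diag,0.116,1/year,package calibration to historical series
death_rate_healthy_mil,0.001,1/year,synthetic placeholder (active-duty mortality)
death_rate_ill_undiag_mil,0.001,1/year,synthetic placeholder (active-duty mortality)
death_rate_ill_diag_mil,0.001,1/year,synthetic placeholder (active-duty mortality)
death_rate_healthy_vet,0.038,1/year,synthetic placeholder (all-era veteran mortality)
death_rate_ill_undiag_vet,0.021,1/year,synthetic placeholder (recent-cohort veteran mortality)
death_rate_ill_diag_vet_recent,0.022,1/year,synthetic placeholder (recent-cohort veteran mortality)
death_rate_ill_diag_vet_pre2000,0.037,1/year,synthetic placeholder (pre-2000 cohort mortality)
cost_per_patient_mil,4500,2012 USD/person/year,main text (Institute of Medicine 2014 report)
cost_per_patient_va,6244,2012 USD/person/year,main text (Institute of Medicine 2014 report)
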