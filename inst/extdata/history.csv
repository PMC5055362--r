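series,year,value,weight
diagnosis_rate_mil,2000,1720,1
diagnosis_rate_mil,2001,2410,1
diagnosis_rate_mil,2002,3690,1
diagnosis_rate_mil,2003,5850,1
diagnosis_rate_mil,2004,8540,1
diagnosis_rate_mil,2005,10800,1
diagnosis_rate_mil,2006,12700,1
diagnosis_rate_mil,2007,14500,1
diagnosis_rate_mil,2008,16300,1
diagnosis_rate_mil,2009,17500,1
diagnosis_rate_mil,2010,17900,1
diagnosis_rate_mil,2011,17800,1
diagnosis_rate_mil,2012,17100,1
diagnosis_rate_mil,2013,15800,1
diagnosis_rate_mil,2014,14000,1
ill_diag_mil,2000,7000,1
ill_diag_mil,2001,7260,1
ill_diag_mil,2002,8380,1
ill_diag_mil,2003,10700,1
ill_diag_mil,2004,14800,1
ill_diag_mil,2005,20300,1
ill_diag_mil,2006,26400,1
ill_diag_mil,2007,32800,1
ill_diag_mil,2008,39500,1
ill_diag_mil,2009,46100,1
ill_diag_mil,2010,52000,1
ill_diag_mil,2011,56700,1
ill_diag_mil,2012,60000,1
ill_diag_mil,2013,61800,1
ill_diag_mil,2014,61800,1
diagnosis_rate_vet,2000,212000,1
diagnosis_rate_vet,2001,174000,1
diagnosis_rate_vet,2002,144000,1
diagnosis_rate_vet,2003,120000,1
diagnosis_rate_vet,2004,102000,1
diagnosis_rate_vet,2005,87700,1
diagnosis_rate_vet,2006,77500,1
diagnosis_rate_vet,2007,70000,1
diagnosis_rate_vet,2008,64800,1
diagnosis_rate_vet,2009,61400,1
diagnosis_rate_vet,2010,58900,1
diagnosis_rate_vet,2011,57000,1
diagnosis_rate_vet,2012,55200,1
diagnosis_rate_vet,2013,53300,1
diagnosis_rate_vet,2014,51000,1
ill_diag_vet_recent,2000,0,1
ill_diag_vet_recent,2001,187000,1
ill_diag_vet_recent,2002,324000,1
ill_diag_vet_recent,2003,424000,1
ill_diag_vet_recent,2004,496000,1
ill_diag_vet_recent,2005,546000,1
ill_diag_vet_recent,2006,581000,1
ill_diag_vet_recent,2007,606000,1
ill_diag_vet_recent,2008,623000,1
ill_diag_vet_recent,2009,635000,1
ill_diag_vet_recent,2010,644000,1
ill_diag_vet_recent,2011,650000,1
ill_diag_vet_recent,2012,655000,1
ill_diag_vet_recent,2013,658000,1
ill_diag_vet_recent,2014,659000,1
ill_diag_vet_pre2000,2000,1e+05,1
ill_diag_vet_pre2000,2001,90100,1
ill_diag_vet_pre2000,2002,81200,1
ill_diag_vet_pre2000,2003,73100,1
ill_diag_vet_pre2000,2004,65900,1
ill_diag_vet_pre2000,2005,59400,1
ill_diag_vet_pre2000,2006,53500,1
ill_diag_vet_pre2000,2007,48200,1
ill_diag_vet_pre2000,2008,43400,1
ill_diag_vet_pre2000,2009,39100,1
ill_diag_vet_pre2000,2010,35200,1
ill_diag_vet_pre2000,2011,31700,1
ill_diag_vet_pre2000,2012,28600,1
ill_diag_vet_pre2000,2013,25800,1
ill_diag_vet_pre2000,2014,23200,1
cost_mil,2000,31500000,1
cost_mil,2001,32700000,1
cost_mil,2002,37700000,1
cost_mil,2003,48100000,1
cost_mil,2004,66700000,1
cost_mil,2005,91200000,1
cost_mil,2006,1.19e+08,1
cost_mil,2007,1.48e+08,1
cost_mil,2008,1.78e+08,1
cost_mil,2009,2.07e+08,1
cost_mil,2010,2.34e+08,1
cost_mil,2011,2.55e+08,1
cost_mil,2012,2.7e+08,1
cost_mil,2013,2.78e+08,1
cost_mil,2014,2.78e+08,1
cost_va,2000,6.24e+08,1
cost_va,2001,1.73e+09,1
cost_va,2002,2.53e+09,1
cost_va,2003,3.11e+09,1
cost_va,2004,3.51e+09,1
cost_va,2005,3.78e+09,1
cost_va,2006,3.96e+09,1
cost_va,2007,4.08e+09,1
cost_va,2008,4.16e+09,1
cost_va,2009,4.21e+09,1
cost_va,2010,4.24e+09,1
cost_va,2011,4.26e+09,1
cost_va,2012,4.27e+09,1
cost_va,2013,4.27e+09,1
cost_va,2014,4.26e+09,1
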