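series,year,value
recruitment,2000,220000
recruitment,2030,220000
deployment_frac,2000,0.010
deployment_frac,2001,0.030
deployment_frac,2002,0.040
deployment_frac,2003,0.080
deployment_frac,2004,0.082
deployment_frac,2005,0.085
deployment_frac,2006,0.088
deployment_frac,2007,0.100
deployment_frac,2008,0.108
deployment_frac,2009,0.088
deployment_frac,2010,0.080
deployment_frac,2011,0.065
deployment_frac,2012,0.050
deployment_frac,2013,0.025
deployment_frac,2014,0.010
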