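measure,group,n,mean,sd
age_years,control,20,74.09,2.67
age_years,observation,20,74.33,2.16
disease_course_years,control,20,6.11,2.07
disease_course_years,observation,20,6.46,2.19
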