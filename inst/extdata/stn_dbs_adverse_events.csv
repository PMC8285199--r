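outcome,group,n,events
dyskinesia,control,20,7
dyskinesia,observation,20,1
motor_fluctuation,control,20,5
motor_fluctuation,observation,20,0
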