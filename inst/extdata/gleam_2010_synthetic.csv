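system,income_group,mt_ch4_2010
tmr,high,1.551282051282051
tmr,upper_middle,0.5
intensive_grazing,high,10
intensive_grazing,upper_middle,22
intensive_grazing,lower_middle,20
intensive_grazing,low,6
extensive,high,5
extensive,upper_middle,12
extensive,lower_middle,21
extensive,low,14.85
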