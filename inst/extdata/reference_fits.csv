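"subject_type","task","M","B","K"
"control","step",0.0019,0.014,0.09
"control","pursuit",0.0019,0.115,0.085
"patient","step",0.0014,0.023,0.082
"patient","pursuit",0.0014,0.03,0.114
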