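"subject_id","group","task","ratio","age","sex","diagnosis","duration_yrs","adl"
"C1","control","pursuit",1.91,46,"M",,,
"C1","control","step",0.03,46,"M",,,
"C10","control","pursuit",0.86,71,"F",,,
"C10","control","step",0.2,71,"F",,,
"C2","control","pursuit",1.34,48,"M",,,
"C2","control","step",0.13,48,"M",,,
"C3","control","pursuit",1.28,63,"M",,,
"C3","control","step",0.11,63,"M",,,
"C4","control","pursuit",1.1,51,"M",,,
"C4","control","step",0.15,51,"M",,,
"C5","control","pursuit",1.28,54,"M",,,
"C5","control","step",0.14,54,"M",,,
"C6","control","pursuit",1.32,52,"M",,,
"C6","control","step",0.24,52,"M",,,
"C7","control","pursuit",1.58,61,"F",,,
"C7","control","step",0.28,61,"F",,,
"C8","control","pursuit",1.08,67,"M",,,
"C8","control","step",0.2,67,"M",,,
"C9","control","pursuit",1.3,68,"F",,,
"C9","control","step",0.17,68,"F",,,
"P1","patient","pursuit",0.75,62,"F","MSA-C",1,1
"P1","patient","step",0.2,62,"F","MSA-C",1,1
"P10","patient","pursuit",0.78,70,"M","SCD",10,1
"P10","patient","step",0.34,70,"M","SCD",10,1
"P11","patient","pursuit",0.23,39,"F","SCD",9,1
"P11","patient","step",0.1,39,"F","SCD",9,1
"P12","patient","pursuit",0.39,65,"F","MSA-C",2,2
"P12","patient","step",0.27,65,"F","MSA-C",2,2
"P13","patient","pursuit",0.5,29,"F","SCD",9,2
"P13","patient","step",0.27,29,"F","SCD",9,2
"P14","patient","pursuit",0.27,76,"F","SCD",5,2
"P14","patient","step",0.28,76,"F","SCD",5,2
"P15","patient","pursuit",0.42,58,"F","SCD",24,2
"P15","patient","step",0.16,58,"F","SCD",24,2
"P16","patient","pursuit",0.56,57,"M","MSA-C",4,2
"P16","patient","step",0.13,57,"M","MSA-C",4,2
"P17","patient","pursuit",0.35,60,"F","MSA-C",9,3
"P17","patient","step",0.31,60,"F","MSA-C",9,3
"P18","patient","pursuit",0.24,71,"M","MSA-C",4,3
"P18","patient","step",0.53,71,"M","MSA-C",4,3
"P19","patient","pursuit",0.38,56,"M","MSA-C",2,3
"P19","patient","step",0.27,56,"M","MSA-C",2,3
"P2","patient","pursuit",1.17,77,"F","SCD",4,1
"P2","patient","step",0.27,77,"F","SCD",4,1
"P3","patient","pursuit",0.69,62,"M","SCD",9,1
"P3","patient","step",0.2,62,"M","SCD",9,1
"P4","patient","pursuit",0.85,72,"M","MSA-C",3,1
"P4","patient","step",0.09,72,"M","MSA-C",3,1
"P5","patient","pursuit",0.57,69,"F","SCD",5,1
"P5","patient","step",0.22,69,"F","SCD",5,1
"P6","patient","pursuit",0.37,65,"F","MSA-C",2,1
"P6","patient","step",0.25,65,"F","MSA-C",2,1
"P7","patient","pursuit",0.37,58,"F","SCD",7,1
"P7","patient","step",0.14,58,"F","SCD",7,1
"P8","patient","pursuit",1.11,34,"F","SCD",9,1
"P8","patient","step",0.32,34,"F","SCD",9,1
"P9","patient","pursuit",0.2,69,"M","SCD",3,1
"P9","patient","step",0.16,69,"M","SCD",3,1
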