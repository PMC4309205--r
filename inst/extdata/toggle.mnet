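# logimc mnet model
input I : 1
A : 1
B : 1
A := { I=1 & B=0 : 1 ; default : 0 }
B := { A=0 : 1 ; default : 0 }
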