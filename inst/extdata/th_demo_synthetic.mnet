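# logimc mnet model
input APC : 1
input IL12_e : 1
input IL4_e : 1
TCR : 1
STAT1 : 1
STAT4 : 1
STAT6 : 1
TBET : 1
GATA3 : 1
IFNG : 1
IL4 : 1
TCR := { APC=1 : 1 ; default : 0 }
STAT1 := { IFNG=1 : 1 ; default : 0 }
STAT4 := { IL12_e=1 & GATA3=0 : 1 ; default : 0 }
STAT6 := { IL4_e=0 & IL4=0 : 0 ; default : 1 }
TBET := { (TCR=1 & STAT1=1 & STAT4=0 & TBET=0 & GATA3=0) | (TCR=1 & STAT1=0 & STAT4=1 & TBET=0 & GATA3=0) | (TCR=1 & STAT1=1 & STAT4=1 & TBET=0 & GATA3=0) | (TCR=1 & STAT1=0 & STAT4=0 & TBET=1 & GATA3=0) | (TCR=1 & STAT1=1 & STAT4=0 & TBET=1 & GATA3=0) | (TCR=1 & STAT1=0 & STAT4=1 & TBET=1 & GATA3=0) | (TCR=1 & STAT1=1 & STAT4=1 & TBET=1 & GATA3=0) : 1 ; default : 0 }
GATA3 := { TCR=1 & STAT6=1 & TBET=0 : 1 ; default : 0 }
IFNG := { TBET=1 : 1 ; default : 0 }
IL4 := { STAT1=0 & GATA3=1 : 1 ; default : 0 }
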