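# inputs: MOD_IN, SIG1, SIG2
MODULATOR = MOD_IN
REC = SIG1 & !MODULATOR
COREC = SIG2
RELAY = REC
KIN = RELAY & !INH
INH = KIN & MODULATOR
CA = KIN & COREC
TF1 = KIN
TF2 = CA
TF3 = COREC | CA
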