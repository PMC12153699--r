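# Synthetic stand-in for the EMA Designated Medical Events list.
# version: synthetic
Disseminated intravascular coagulation
Ventricular arrhythmia
Cardiogenic shock
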