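# Synthetic stand-in for the EMA Important Medical Events list.
# The official IME list is distributed by the EMA; supply it here for a
# production analysis, one Preferred Term per line.
# version: synthetic-27.1
Brugada syndrome
Electrocardiogram QT prolonged
Atrial fibrillation
Ventricular arrhythmia
Cardiac failure
Left ventricular failure
Cardiogenic shock
Cardiomyopathy
Cardiotoxicity
Myocarditis
Pericarditis
Myocardial infarction
Acute coronary syndrome
Coronary artery stenosis
Disseminated intravascular coagulation
Pulmonary embolism
Deep vein thrombosis
Cerebral ischaemia
Splenic infarction
Hemiparesis
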