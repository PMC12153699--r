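# Synthetic stand-in for per-group labeled (expected) adverse reaction
# lists, i.e. PTs present in each product's FDA Full Prescribing
# Information, Adverse Reactions section.  Replace with lists extracted
# from the current labels for a production analysis.
version: synthetic
groups:
  "D+T":
    - Atrioventricular block complete
    - Cardiac failure
    - Cardiomyopathy
    - Ejection fraction decreased
    - Pulmonary embolism
    - Deep vein thrombosis
  "V+C":
    - Electrocardiogram QT prolonged
    - Cardiomyopathy
    - Ejection fraction decreased
    - Atrial fibrillation
  "E+B":
    - Electrocardiogram QT prolonged
    - Left ventricular failure
    - Ejection fraction decreased
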