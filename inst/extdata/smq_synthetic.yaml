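# Synthetic narrow-scope SMQ fixture vocabulary.  The licensed MedDRA SMQ
# contents are not redistributable; replace these PT lists with the
# licensed narrow-scope sets for a production analysis.
version: synthetic-fixture
smqs:
  "Bradyarrhythmias (incl conduction defects and disorders of sinus node function)":
    - Brugada syndrome
    - Electrocardiogram QT prolonged
    - Atrioventricular block complete
    - Bundle branch block right
    - Sinus bradycardia
  "Cardiac failure":
    - Cardiac failure
    - Left ventricular failure
    - Cardiogenic shock
    - Pulmonary oedema
  "Cardiomyopathy":
    - Cardiomyopathy
    - Cardiotoxicity
    - Ejection fraction decreased
    - Stress cardiomyopathy
  "Embolic and thrombotic events":
    - Disseminated intravascular coagulation
    - Pulmonary embolism
    - Deep vein thrombosis
    - Cerebral ischaemia
    - Hemiparesis
    - Splenic infarction
    - Thrombosis
  "Ischaemic heart disease":
    - Myocardial infarction
    - Coronary artery stenosis
    - Acute coronary syndrome
    - Angina pectoris
  "Noninfectious myocarditis/pericarditis":
    - Myocarditis
    - Pericarditis
  "Tachyarrhythmias (incl supraventricular and ventricular tachyarrhythmias)":
    - Atrial fibrillation
    - Ventricular arrhythmia
    - Sinus tachycardia
    - Atrial flutter
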