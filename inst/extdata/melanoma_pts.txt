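# Indication Preferred Terms accepted as melanoma.
# version: synthetic
Malignant melanoma
Melanoma
Metastatic melanoma
Malignant melanoma stage III
Malignant melanoma stage IV
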