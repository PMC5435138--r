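variable,outcome_exposed,outcome_unexposed,control_exposed,control_unexposed
copd,52,299,6979,118410
renal_disease,70,281,10670,114719
naloxone,19,332,747,124642
pca,5,346,170,125219
sepsis,9,342,959,124430
high_dose_rocuronium,13,338,1278,124111
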