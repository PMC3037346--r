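heart failure
congestive heart failure
new york heart association
left ventricular ejection fraction
chf
chronic heart failure
cardiomyopathy
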