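# Generator preset mirroring the scale of the FARSEEING real-world study
# data: 15 subjects with 12-h ADL recordings (15 x 12 = 180 monitored hours)
# and 143 fall recordings over 46 subjects. Simulating this preset in full is
# expensive; it documents the reference scale.
nSubjects: 46
nAdlSubjects: 15
adlHoursPerSubject: 12
nFallsTotal: 143
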