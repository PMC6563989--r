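# Sex of the animals among sex-disclosing DMD intervention studies,
# % per model group.
category,mdx mouse,GRMD dog
male,53.3,0.0
female,20.0,0.0
both,26.7,100.0
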