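file	md5
crystal_descriptors.tsv	4b22fe9ee80d6ee421d0280c318ebc65
cst_events.tsv	b7cbe859d9e91741816c541d139ae6ba
forced_oxidation.tsv	807aa5be73fa4cf2caa7d206ced586bc
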