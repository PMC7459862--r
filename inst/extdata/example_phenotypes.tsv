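taxon	oxygen_class	gram_class
Escherichia	facultative_anaerobic	negative
Escherichia coli	facultative_anaerobic	negative
Pseudomonas	aerobic	negative
Bacillus	aerobic	positive
Clostridium	anaerobic	positive
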