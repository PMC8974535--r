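country,prevalence_2025_pct
Bangladesh,27.2
Bhutan,21.5
India,27.1
Nepal,25.6
Pakistan,23.5
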