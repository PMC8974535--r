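country,y2020,y2021,y2022,y2023,y2024,y2025,average_printed
Bangladesh,38,78,121,168,217,223,141
Bhutan,287,601,943,1321,1740,1782,1113
India,267,555,868,1209,1582,1625,1018
Nepal,51,106,167,234,307,318,197
Pakistan,104,217,341,476,625,643,401
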