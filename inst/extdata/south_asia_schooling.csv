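country,y2020,y2021,y2022,y2023,y2024,y2025,total_printed
Bangladesh,7.1,14,21,28,35,35,140
Bhutan,0.2,0.3,0.5,0.7,0.9,0.8,3.4
India,359,721,1092,1470,1865,1860,7367
Nepal,4,8,13,17,21,20,83
Pakistan,46,94,143,194,247,247,971
Total,416,837,1269,1709,2169,2163,8563
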