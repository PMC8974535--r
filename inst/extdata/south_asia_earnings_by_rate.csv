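rate_pct,y2020,y2021,y2022,y2023,y2024,y2025,total_printed
3,5750,11879,18489,25561,33286,34062,129028
5,2879,5956,9282,12850,16755,17166,64888
10,677,1404,2195,3048,3986,4094,15404
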