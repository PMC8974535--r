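country,y2020,y2021,y2022,y2023,y2024,y2025,total_printed
Bangladesh,32,67,103,140,180,184,706
Bhutan,1,3,4,6,7,7,28
India,2640,5457,8501,11760,15329,15702,59390
Nepal,10,20,31,43,55,56,215
Pakistan,195,409,643,901,1183,1217,4549
Total,2879,5956,9282,12850,16755,17166,64888
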