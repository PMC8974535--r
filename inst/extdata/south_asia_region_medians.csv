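region,median_wage_increase_per_haz_pct,n_countries
Africa,2.4,47
Americas,4.5,30
Eastern-Mediterranean,2.4,20
European,2.1,29
South-East Asia,2.7,11
Western-Pacific,3.5,19
Overall,2.4,156
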