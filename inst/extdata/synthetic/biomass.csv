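# synthetic spawner-biomass series (invented values, not survey data)
"year","sardine","anchovy"
2013,680000,1900000
2014,510000,2400000
2015,420000,1600000
2016,250000,2100000
2017,310000,2800000
2018,180000,1700000
2019,140000,2200000
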