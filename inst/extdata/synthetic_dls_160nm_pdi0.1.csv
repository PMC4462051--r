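"lower_nm","upper_nm","percent"
18.5879189114656,24.2446201708233,1.27339203700307e-07
24.2446201708233,31.6227766016838,1.7103240437978e-05
31.6227766016838,41.2462638290135,0.00111708552887859
41.2462638290135,53.7983840344369,0.0356288787032169
53.7983840344369,70.1703828670383,0.557563298108661
70.1703828670383,91.5247310877389,4.30281293532557
91.5247310877389,119.377664171444,16.4531883237643
119.377664171444,155.706840475373,31.2911655628237
155.706840475373,203.091762090474,29.6581877371549
203.091762090474,264.896928761053,14.0069309478002
264.896928761053,345.510729459222,3.28856071150271
345.510729459222,450.657033774547,0.382303946503519
450.657033774547,587.801607227491,0.0218998506551183
587.801607227491,766.682207454621,0.000615061963465515
766.682207454621,1000,8.42958615611327e-06
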