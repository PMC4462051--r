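"lower_nm","upper_nm","percent"
10.9260086111738,14.25102670303,3.70490114429477e-08
14.25102670303,18.5879189114656,5.88078518073205e-06
18.5879189114656,24.2446201708233,0.000453532263011193
24.2446201708233,31.6227766016838,0.0170625583500911
31.6227766016838,41.2462638290135,0.31460194187974
41.2462638290135,53.7983840344369,2.85718992000181
53.7983840344369,70.1703828670383,12.8441029148863
70.1703828670383,91.5247310877389,28.6960223578691
91.5247310877389,119.377664171444,31.9424923849686
119.377664171444,155.706840475373,17.7213301421174
155.706840475373,203.091762090474,4.89098003808609
203.091762090474,264.896928761053,0.669083862764786
264.896928761053,345.510729459222,0.0451542806763541
345.510729459222,450.657033774547,0.00149575416024265
450.657033774547,587.801607227491,2.42036304667164e-05
587.801607227491,766.682207454621,1.90511839638856e-07
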