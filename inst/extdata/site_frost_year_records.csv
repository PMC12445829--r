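site,year,window_tmin,window_tmin_doy,window_amplitude,leafout_doy
low,1940,-0.8,138,6.4,130
low,1977,0.8,129,6.0,134
low,1978,0.0,133,5.2,138
low,1987,-1.6,134,8.8,130
low,2011,0.4,124,10.8,116
low,2012,-1.6,138,14.4,125
high,1940,-2.4,138,6.4,141
high,1946,-2.0,136,10.0,128
high,1975,-0.8,152,2.8,140
high,1977,1.2,152,12.0,143
high,1991,-1.2,144,8.8,149
high,1995,-3.6,135,12.4,138
high,2012,-2.8,138,13.2,132
high,2016,-2.0,136,6.4,141
high,2017,0.4,139,9.6,136
high,2020,-2.0,133,9.6,124
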