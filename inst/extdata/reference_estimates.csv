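window,trait,n_total,pct_total,n_early,pct_early,n_late,pct_late,ratio
lifetime,ketamine,162,11.7,125,16.3,37,5.7,2.9
lifetime,ecstasy,146,11.7,105,15.0,41,7.5,2.0
lifetime,marijuana,152,10.5,104,13.6,48,6.4,2.1
lifetime,methamphetamine,79,6.0,64,10.2,15,2.7,3.8
lifetime,heroin,43,2.7,34,4.3,9,1.1,3.9
lifetime,any_illegal,277,21.2,206,28.8,71,11.5,2.5
lifetime,any_club,245,18.0,180,23.6,65,10.6,2.2
lifetime,any_hard,85,6.5,70,11.1,15,2.7,4.1
lifetime,single,103,8.2,79,6.1,24,2.0,3.1
lifetime,poly_no_hard,104,7.6,72,5.6,32,2.0,2.8
lifetime,poly_hard,70,5.2,55,4.9,15,1.1,4.5
past_year,ketamine,67,4.3,47,5.6,20,2.9,1.9
past_year,ecstasy,53,4.0,32,3.8,21,4.1,0.9
past_year,marijuana,56,3.8,33,4.7,23,2.7,1.7
past_year,methamphetamine,29,2.9,22,4.4,7,1.9,2.3
past_year,heroin,22,0.9,16,1.0,6,0.7,1.4
past_year,any_illegal,130,8.9,90,11.1,40,6.4,1.7
past_year,any_club,103,7.0,69,8.0,34,5.5,1.5
past_year,any_hard,42,3.2,31,4.9,11,2.0,2.5
past_year,single,63,4.5,50,3.5,13,1.1,3.2
past_year,poly_no_hard,44,3.0,26,2.0,18,1.0,2.0
past_year,poly_hard,26,1.8,17,1.2,9,0.7,1.7
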