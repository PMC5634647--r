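subject,trial,block,group,start_state,first_choice,second_state,terminal_state,reward,contingency_id,contingency_changed,reward_flip,high_state
1,1,1,1,S0,A2,S2,S4,0.72377204742390433,0,FALSE,FALSE,S3
1,2,1,1,S1,,S1,S3,0.46430322526137824,0,FALSE,FALSE,S3
1,3,1,1,S2,,S2,S4,0.45954562028185242,0,FALSE,FALSE,S3
1,4,1,1,S0,A2,S2,S3,0.33401280301764358,1,TRUE,FALSE,S3
1,5,1,1,S2,,S2,S3,0.82200581810533024,1,FALSE,TRUE,S4
1,6,1,1,S0,A2,S2,S3,0.61593334143794687,1,FALSE,FALSE,S4
1,7,1,1,S0,A2,S2,S3,0.95030397170137582,1,FALSE,FALSE,S4
1,8,1,1,S0,A2,S2,S3,0.86335503749282827,1,FALSE,FALSE,S4
1,9,1,1,S1,,S1,S3,0.78354687976524517,0,TRUE,FALSE,S4
1,10,1,1,S1,,S1,S3,0.052755042274307024,0,FALSE,TRUE,S3
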