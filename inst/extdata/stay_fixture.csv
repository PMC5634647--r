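subject,trial,block,group,start_state,first_choice,second_state,terminal_state,reward,contingency_id,contingency_changed,reward_flip,high_state
1,1,1,1,S1,,S1,S3,0.90000000000000002,0,FALSE,FALSE,S3
1,2,1,1,S0,A1,S1,S3,0.80000000000000004,0,FALSE,FALSE,S3
1,3,1,1,S0,A2,S2,S4,0.20000000000000001,0,FALSE,FALSE,S3
1,4,1,1,S2,,S2,S3,0.84999999999999998,1,TRUE,FALSE,S3
1,5,1,1,S0,A1,S1,S4,0.10000000000000001,1,FALSE,FALSE,S3
1,6,1,1,S0,A1,S1,S4,0.14999999999999999,1,FALSE,FALSE,S3
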