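participant_id,variant,block,item_id,difficulty,save_eligible,saved,test_type,confidence_condition,confidence_raw,choice,hint_shown,recall,points_delta
p01,exp1,1,i01,easy,true,false,forced,absent,,absent,false,1,20
p01,exp1,1,i02,difficult,true,true,free,absent,,ask,true,1,17
p01,exp1,1,i03,difficult,true,true,forced,absent,,absent,false,0,-20
p01,exp1,1,i04,easy,true,false,free,absent,,self,false,1,20
p01,exp1,1,i05,difficult,false,false,free,absent,,ask,false,0,-23
p01,exp1,1,i06,easy,true,true,free,absent,,ask,true,1,17
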