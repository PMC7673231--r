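subject_id,group,word_id,target_tone,onset_st,mid_st,offset_st
toy,NH,w01,1,0,1,2
toy,NH,w02,1,1,1,2
toy,NH,w03,1,0.5,1,2.5
toy,NH,w04,2,2,1,2
toy,NH,w05,2,3,1,2
toy,NH,w06,2,2.5,1,2.5
toy,NH,w07,3,0,1,0
toy,NH,w08,3,1,1,0
toy,NH,w09,3,0.5,1,0.5
toy,NH,w10,4,2,1,0
toy,NH,w11,4,3,1,0
toy,NH,w12,4,2.5,1,0.5
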