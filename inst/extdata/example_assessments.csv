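subject_id,rater_id,CN,AD,BVFTD,SD,PNFA,PSP,DLB
S001,model,10.2,74.3,2.1,1.0,0.8,2.4,9.2
S001,radiologist1,30.0,60.0,2.0,1.0,1.0,2.0,4.0
S002,model,46.6,17.6,8.0,4.1,3.9,6.1,13.7
S002,radiologist1,45.0,45.0,3.0,1.0,1.0,2.0,3.0
S003,model,12.0,41.8,7.5,3.6,4.0,8.1,23.0
S003,radiologist1,20.0,70.0,2.0,2.0,2.0,2.0,2.0
S004,model,58.9,11.5,6.4,3.3,3.1,5.8,11.0
S004,radiologist1,70.0,20.0,2.0,2.0,2.0,2.0,2.0
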