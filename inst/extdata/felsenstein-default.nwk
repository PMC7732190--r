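(((out1:2,out2:2):0.07,out3:2):0.07,((inA1:0.2,inA2:0.2):0.07,inA3:0.2):0.07,(((inB1:0.2,inB2:0.2):0.07,inB3:0.2):0.07,((foc1:1.7,foc2:1.7):0.07,foc3:0.55):0.07):0.07);
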