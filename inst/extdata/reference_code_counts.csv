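classifier,diversion,tp,fp,fn,tn
code,incontinent,270,191,8,428228
code,continent,222,237,0,428238
model_threshold,incontinent,277,1614,1,426805
model_threshold,continent,222,80,0,428395
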