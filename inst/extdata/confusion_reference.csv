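true,N,A,O,~
N,4724,16,293,17
A,37,519,167,15
O,613,97,1715,31
~,74,15,50,145
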