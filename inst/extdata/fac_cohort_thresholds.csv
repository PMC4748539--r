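sample,histology,morphology,edu,tunel
059,ductal,5,NA,5
068,ductal,3,5,3
070,lobular,5,5,5
071,lobular,5,5,5
072,ductal,2,2,2
083,ductal,5,7,5
089,ductal,3,7,5
090,ductal,2,3,2
102,lobular,2,5,5
112,ductal,3,3,3
118,ductal,3,3,5
119,ductal,5,3,3
121,lobular,3,5,3
135,ductal,3,3,3
141,ductal,3,5,5
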