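sample,ground_truth,mp_vat,mp_vat2,c_vat,mp_net
1,170,287,396,268,175
2,91,163,204,166,100
3,132,337,389,353,135
4,53,122,153,128,65
5,131,258,392,284,132
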