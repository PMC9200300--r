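sample,ground_truth,mp_vat,mp_vat2,c_vat,mp_net
1,19,29,602,2951,17
2,5,19,21,2851,6
3,8,11,14,185,8
4,6,7,326,256,5
5,7,8,18,355,6
6,5,16,297,15,7
7,383,655,609,46066,294
8,2,64,9,283,2
9,4,39,34,26,6
10,223,564,449,22819,230
11,11,38,28,653,13
12,26,42,49,261,27
13,74,268,138,5378,92
14,94,294,3145,20943,114
15,138,288,1301,2304,135
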