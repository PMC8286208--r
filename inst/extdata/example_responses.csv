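item1,item2,item3,item4,item5,injury_group
7,7,7,7,7,TBI
1,1,1,1,1,TBI
3,4,5,6,2,TBI
4,4,4,4,4,SCI
2,3,3,4,2,SCI
6,5,6,7,5,SCI
5,5,4,6,3,Burn
2,2,3,3,1,Burn
6,6,7,6,6,Burn
4,5,3,4,5,TBI
3,3,2,4,1,SCI
5,6,6,5,4,Burn
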