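individual_id,age,alive,stage,eggs_laid,kills_egg,kills_immature,kills_adult
f1,0,1,egg,0,0,0,0
f1,1,1,larva,0,1,1,0
f1,2,1,protonymph,0,2,1,1
f1,3,1,adult,2,3,2,1
f1,4,1,adult,3,4,2,2
f1,5,0,adult,0,0,0,0
f2,0,1,egg,0,0,0,0
f2,1,1,larva,0,1,0,0
f2,2,1,protonymph,0,1,2,0
f2,3,1,adult,1,2,2,1
f2,4,0,adult,0,0,0,0
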