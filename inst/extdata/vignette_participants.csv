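participant_id,age_group,list_version,round,position,word,bet,recalled
A,other,unknown,1,1,a,10,1
A,other,unknown,1,2,b,10,1
A,other,unknown,1,3,c,10,1
A,other,unknown,1,4,d,10,1
A,other,unknown,1,5,e,10,0
A,other,unknown,1,6,f,10,0
A,other,unknown,1,7,g,5,0
A,other,unknown,1,8,h,10,0
A,other,unknown,1,9,i,10,0
A,other,unknown,1,10,j,10,0
A,other,unknown,1,11,k,10,0
A,other,unknown,1,12,l,10,0
B,other,unknown,1,1,a,10,1
B,other,unknown,1,2,b,10,1
B,other,unknown,1,3,c,3,1
B,other,unknown,1,4,d,3,0
B,other,unknown,1,5,e,3,0
B,other,unknown,1,6,f,1,0
B,other,unknown,1,7,g,1,0
B,other,unknown,1,8,h,1,0
B,other,unknown,1,9,i,1,0
B,other,unknown,1,10,j,2,0
B,other,unknown,1,11,k,1,0
B,other,unknown,1,12,l,1,0
C,other,unknown,1,1,b,1,1
C,other,unknown,1,2,c,1,1
C,other,unknown,1,3,d,4,0
C,other,unknown,1,4,e,3,0
C,other,unknown,1,5,f,4,0
C,other,unknown,1,6,g,4,0
C,other,unknown,1,7,h,4,0
C,other,unknown,1,8,i,3,0
C,other,unknown,1,9,j,4,0
C,other,unknown,1,10,k,3,0
C,other,unknown,1,11,l,3,0
D,other,unknown,1,1,b,5,1
D,other,unknown,1,2,c,4,1
D,other,unknown,1,3,d,1,1
D,other,unknown,1,4,e,3,1
D,other,unknown,1,5,f,1,1
D,other,unknown,1,6,g,2,1
D,other,unknown,1,7,h,10,0
D,other,unknown,1,8,i,6,0
D,other,unknown,1,9,j,5,0
D,other,unknown,1,10,k,5,0
D,other,unknown,1,11,l,10,0
E,other,unknown,1,1,a,4,1
E,other,unknown,1,2,b,4,1
E,other,unknown,1,3,c,4,1
E,other,unknown,1,4,d,4,1
E,other,unknown,1,5,e,4,0
E,other,unknown,1,6,f,2,0
E,other,unknown,1,7,g,2,0
E,other,unknown,1,8,h,2,0
E,other,unknown,1,9,i,2,0
E,other,unknown,1,10,j,2,0
E,other,unknown,1,11,k,2,0
E,other,unknown,1,12,l,2,0
F,other,unknown,1,1,a,10,1
F,other,unknown,1,2,b,10,1
F,other,unknown,1,3,c,10,1
F,other,unknown,1,4,d,10,1
F,other,unknown,1,5,e,10,0
F,other,unknown,1,6,f,1,0
F,other,unknown,1,7,g,1,0
F,other,unknown,1,8,h,1,0
F,other,unknown,1,9,i,1,0
F,other,unknown,1,10,j,1,0
F,other,unknown,1,11,k,1,0
F,other,unknown,1,12,l,1,0
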