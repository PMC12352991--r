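block,sex,tooth_fdi,stage,score,maturity_score,dental_age
score,F,31,UNFORMED,0,NA,NA
score,F,31,A,1.2,NA,NA
score,F,31,B,2.2,NA,NA
score,F,31,C,3.3000000000000003,NA,NA
score,F,31,D,4.8,NA,NA
score,F,31,E,6.3,NA,NA
score,F,31,F,7.800000000000001,NA,NA
score,F,31,G,9.200000000000001,NA,NA
score,F,31,H,10,NA,NA
score,F,32,UNFORMED,0,NA,NA
score,F,32,A,1.2,NA,NA
score,F,32,B,2.2,NA,NA
score,F,32,C,3.3000000000000003,NA,NA
score,F,32,D,4.8,NA,NA
score,F,32,E,6.3,NA,NA
score,F,32,F,7.800000000000001,NA,NA
score,F,32,G,9.200000000000001,NA,NA
score,F,32,H,10,NA,NA
score,F,33,UNFORMED,0,NA,NA
score,F,33,A,1.44,NA,NA
score,F,33,B,2.64,NA,NA
score,F,33,C,3.96,NA,NA
score,F,33,D,5.76,NA,NA
score,F,33,E,7.5600000000000005,NA,NA
score,F,33,F,9.36,NA,NA
score,F,33,G,11.040000000000001,NA,NA
score,F,33,H,12,NA,NA
score,F,34,UNFORMED,0,NA,NA
score,F,34,A,1.68,NA,NA
score,F,34,B,3.08,NA,NA
score,F,34,C,4.62,NA,NA
score,F,34,D,6.72,NA,NA
score,F,34,E,8.82,NA,NA
score,F,34,F,10.92,NA,NA
score,F,34,G,12.88,NA,NA
score,F,34,H,14,NA,NA
score,F,35,UNFORMED,0,NA,NA
score,F,35,A,1.92,NA,NA
score,F,35,B,3.52,NA,NA
score,F,35,C,5.28,NA,NA
score,F,35,D,7.68,NA,NA
score,F,35,E,10.08,NA,NA
score,F,35,F,12.48,NA,NA
score,F,35,G,14.72,NA,NA
score,F,35,H,16,NA,NA
score,F,36,UNFORMED,0,NA,NA
score,F,36,A,2.16,NA,NA
score,F,36,B,3.96,NA,NA
score,F,36,C,5.94,NA,NA
score,F,36,D,8.64,NA,NA
score,F,36,E,11.34,NA,NA
score,F,36,F,14.040000000000001,NA,NA
score,F,36,G,16.560000000000002,NA,NA
score,F,36,H,18,NA,NA
score,F,37,UNFORMED,0,NA,NA
score,F,37,A,2.4,NA,NA
score,F,37,B,4.4,NA,NA
score,F,37,C,6.6000000000000005,NA,NA
score,F,37,D,9.6,NA,NA
score,F,37,E,12.6,NA,NA
score,F,37,F,15.600000000000001,NA,NA
score,F,37,G,18.400000000000002,NA,NA
score,F,37,H,20,NA,NA
score,M,31,UNFORMED,0,NA,NA
score,M,31,A,1,NA,NA
score,M,31,B,2,NA,NA
score,M,31,C,3,NA,NA
score,M,31,D,4.5,NA,NA
score,M,31,E,6,NA,NA
score,M,31,F,7.5,NA,NA
score,M,31,G,9,NA,NA
score,M,31,H,10,NA,NA
score,M,32,UNFORMED,0,NA,NA
score,M,32,A,1,NA,NA
score,M,32,B,2,NA,NA
score,M,32,C,3,NA,NA
score,M,32,D,4.5,NA,NA
score,M,32,E,6,NA,NA
score,M,32,F,7.5,NA,NA
score,M,32,G,9,NA,NA
score,M,32,H,10,NA,NA
score,M,33,UNFORMED,0,NA,NA
score,M,33,A,1.2000000000000002,NA,NA
score,M,33,B,2.4000000000000004,NA,NA
score,M,33,C,3.5999999999999996,NA,NA
score,M,33,D,5.4,NA,NA
score,M,33,E,7.199999999999999,NA,NA
score,M,33,F,9,NA,NA
score,M,33,G,10.8,NA,NA
score,M,33,H,12,NA,NA
score,M,34,UNFORMED,0,NA,NA
score,M,34,A,1.4000000000000001,NA,NA
score,M,34,B,2.8000000000000003,NA,NA
score,M,34,C,4.2,NA,NA
score,M,34,D,6.3,NA,NA
score,M,34,E,8.4,NA,NA
score,M,34,F,10.5,NA,NA
score,M,34,G,12.6,NA,NA
score,M,34,H,14,NA,NA
score,M,35,UNFORMED,0,NA,NA
score,M,35,A,1.6,NA,NA
score,M,35,B,3.2,NA,NA
score,M,35,C,4.8,NA,NA
score,M,35,D,7.2,NA,NA
score,M,35,E,9.6,NA,NA
score,M,35,F,12,NA,NA
score,M,35,G,14.4,NA,NA
score,M,35,H,16,NA,NA
score,M,36,UNFORMED,0,NA,NA
score,M,36,A,1.8,NA,NA
score,M,36,B,3.6,NA,NA
score,M,36,C,5.3999999999999995,NA,NA
score,M,36,D,8.1,NA,NA
score,M,36,E,10.799999999999999,NA,NA
score,M,36,F,13.5,NA,NA
score,M,36,G,16.2,NA,NA
score,M,36,H,18,NA,NA
score,M,37,UNFORMED,0,NA,NA
score,M,37,A,2,NA,NA
score,M,37,B,4,NA,NA
score,M,37,C,6,NA,NA
score,M,37,D,9,NA,NA
score,M,37,E,12,NA,NA
score,M,37,F,15,NA,NA
score,M,37,G,18,NA,NA
score,M,37,H,20,NA,NA
conversion,F,NA,NA,NA,0,2.8
conversion,F,NA,NA,NA,10,4.7
conversion,F,NA,NA,NA,20,6.2
conversion,F,NA,NA,NA,30,7.5
conversion,F,NA,NA,NA,40,8.5
conversion,F,NA,NA,NA,50,9.5
conversion,F,NA,NA,NA,60,10.5
conversion,F,NA,NA,NA,70,11.5
conversion,F,NA,NA,NA,80,12.7
conversion,F,NA,NA,NA,90,14.1
conversion,F,NA,NA,NA,100,15.8
conversion,M,NA,NA,NA,0,3
conversion,M,NA,NA,NA,10,5
conversion,M,NA,NA,NA,20,6.5
conversion,M,NA,NA,NA,30,7.8
conversion,M,NA,NA,NA,40,8.8
conversion,M,NA,NA,NA,50,9.8
conversion,M,NA,NA,NA,60,10.8
conversion,M,NA,NA,NA,70,11.8
conversion,M,NA,NA,NA,80,13
conversion,M,NA,NA,NA,90,14.4
conversion,M,NA,NA,NA,100,16
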