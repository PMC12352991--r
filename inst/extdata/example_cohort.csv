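subject_id,sex,ca_years,rater_id,session_id,tooth_fdi,apex_status,root_fraction,demirjian_stage
S0001,F,8.31,R1,S1,31,closed,NA,H
S0001,F,8.31,R1,S1,41,closed,NA,NA
S0001,F,8.31,R1,S1,16,closed,NA,NA
S0001,F,8.31,R1,S1,26,closed,NA,NA
S0001,F,8.31,R1,S1,36,closed,NA,H
S0001,F,8.31,R1,S1,46,open,0.957,NA
S0001,F,8.31,R1,S1,32,open,0.899,G
S0001,F,8.31,R1,S1,42,open,0.913,NA
S0001,F,8.31,R1,S1,11,open,0.806,NA
S0001,F,8.31,R1,S1,21,open,0.854,NA
S0001,F,8.31,R1,S1,12,open,0.775,NA
S0001,F,8.31,R1,S1,22,open,0.758,NA
S0001,F,8.31,R1,S1,33,open,0.498,D
S0001,F,8.31,R1,S1,43,open,0.454,NA
S0001,F,8.31,R1,S1,34,open,0.53,E
S0001,F,8.31,R1,S1,44,open,0.501,NA
S0001,F,8.31,R1,S1,14,open,0.301,NA
S0001,F,8.31,R1,S1,24,open,0.286,NA
S0001,F,8.31,R1,S1,35,open,0.259,C
S0001,F,8.31,R1,S1,45,open,0.251,NA
S0001,F,8.31,R1,S1,13,open,0.129,NA
S0001,F,8.31,R1,S1,23,open,0.156,NA
S0001,F,8.31,R1,S1,17,open,0.047,NA
S0001,F,8.31,R1,S1,27,open,0,NA
S0001,F,8.31,R1,S1,37,open,0,A
S0001,F,8.31,R1,S1,47,open,0.035,NA
S0002,M,8.56,R1,S1,31,open,0.87,G
S0002,M,8.56,R1,S1,41,open,0.927,NA
S0002,M,8.56,R1,S1,16,open,0.796,NA
S0002,M,8.56,R1,S1,26,open,0.898,NA
S0002,M,8.56,R1,S1,36,open,0.902,G
S0002,M,8.56,R1,S1,46,open,0.857,NA
S0002,M,8.56,R1,S1,32,open,0.806,F
S0002,M,8.56,R1,S1,42,open,0.767,NA
S0002,M,8.56,R1,S1,11,open,0.728,NA
S0002,M,8.56,R1,S1,21,open,0.653,NA
S0002,M,8.56,R1,S1,12,open,0.632,NA
S0002,M,8.56,R1,S1,22,open,0.613,NA
S0002,M,8.56,R1,S1,33,open,0.396,D
S0002,M,8.56,R1,S1,43,open,0.331,NA
S0002,M,8.56,R1,S1,34,open,0.401,D
S0002,M,8.56,R1,S1,44,open,0.386,NA
S0002,M,8.56,R1,S1,14,open,0.214,NA
S0002,M,8.56,R1,S1,24,open,0.215,NA
S0002,M,8.56,R1,S1,35,open,0.07,B
S0002,M,8.56,R1,S1,45,open,0.12,NA
S0002,M,8.56,R1,S1,13,open,0.057,NA
S0002,M,8.56,R1,S1,23,open,0.017,NA
S0002,M,8.56,R1,S1,17,open,0,NA
S0002,M,8.56,R1,S1,27,open,0,NA
S0002,M,8.56,R1,S1,37,open,0,A
S0002,M,8.56,R1,S1,47,open,0,NA
S0003,F,10.355,R1,S1,31,closed,NA,H
S0003,F,10.355,R1,S1,41,closed,NA,NA
S0003,F,10.355,R1,S1,16,closed,NA,NA
S0003,F,10.355,R1,S1,26,closed,NA,NA
S0003,F,10.355,R1,S1,36,closed,NA,H
S0003,F,10.355,R1,S1,46,closed,NA,NA
S0003,F,10.355,R1,S1,32,closed,NA,H
S0003,F,10.355,R1,S1,42,closed,NA,NA
S0003,F,10.355,R1,S1,11,closed,NA,NA
S0003,F,10.355,R1,S1,21,closed,NA,NA
S0003,F,10.355,R1,S1,12,closed,NA,NA
S0003,F,10.355,R1,S1,22,closed,NA,NA
S0003,F,10.355,R1,S1,33,open,0.89,G
S0003,F,10.355,R1,S1,43,open,0.701,NA
S0003,F,10.355,R1,S1,34,open,0.805,F
S0003,F,10.355,R1,S1,44,open,0.782,NA
S0003,F,10.355,R1,S1,14,open,0.679,NA
S0003,F,10.355,R1,S1,24,open,0.627,NA
S0003,F,10.355,R1,S1,35,open,0.561,E
S0003,F,10.355,R1,S1,45,open,0.552,NA
S0003,F,10.355,R1,S1,13,open,0.457,NA
S0003,F,10.355,R1,S1,23,open,0.483,NA
S0003,F,10.355,R1,S1,17,open,0.327,NA
S0003,F,10.355,R1,S1,27,open,0.28,NA
S0003,F,10.355,R1,S1,37,open,0.308,C
S0003,F,10.355,R1,S1,47,open,0.273,NA
S0004,M,10.662,R1,S1,31,closed,NA,H
S0004,M,10.662,R1,S1,41,closed,NA,NA
S0004,M,10.662,R1,S1,16,closed,NA,NA
S0004,M,10.662,R1,S1,26,closed,NA,NA
S0004,M,10.662,R1,S1,36,closed,NA,H
S0004,M,10.662,R1,S1,46,closed,NA,NA
S0004,M,10.662,R1,S1,32,closed,NA,H
S0004,M,10.662,R1,S1,42,closed,NA,NA
S0004,M,10.662,R1,S1,11,closed,NA,NA
S0004,M,10.662,R1,S1,21,closed,NA,NA
S0004,M,10.662,R1,S1,12,closed,NA,NA
S0004,M,10.662,R1,S1,22,closed,NA,NA
S0004,M,10.662,R1,S1,33,open,0.921,G
S0004,M,10.662,R1,S1,43,open,0.892,NA
S0004,M,10.662,R1,S1,34,open,0.848,G
S0004,M,10.662,R1,S1,44,open,0.901,NA
S0004,M,10.662,R1,S1,14,open,0.745,NA
S0004,M,10.662,R1,S1,24,open,0.801,NA
S0004,M,10.662,R1,S1,35,open,0.58,E
S0004,M,10.662,R1,S1,45,open,0.705,NA
S0004,M,10.662,R1,S1,13,open,0.511,NA
S0004,M,10.662,R1,S1,23,open,0.586,NA
S0004,M,10.662,R1,S1,17,open,0.362,NA
S0004,M,10.662,R1,S1,27,open,0.439,NA
S0004,M,10.662,R1,S1,37,open,0.395,D
S0004,M,10.662,R1,S1,47,open,0.424,NA
S0005,F,12.827,R1,S1,31,closed,NA,H
S0005,F,12.827,R1,S1,41,closed,NA,NA
S0005,F,12.827,R1,S1,16,closed,NA,NA
S0005,F,12.827,R1,S1,26,closed,NA,NA
S0005,F,12.827,R1,S1,36,closed,NA,H
S0005,F,12.827,R1,S1,46,closed,NA,NA
S0005,F,12.827,R1,S1,32,closed,NA,H
S0005,F,12.827,R1,S1,42,closed,NA,NA
S0005,F,12.827,R1,S1,11,closed,NA,NA
S0005,F,12.827,R1,S1,21,closed,NA,NA
S0005,F,12.827,R1,S1,12,closed,NA,NA
S0005,F,12.827,R1,S1,22,closed,NA,NA
S0005,F,12.827,R1,S1,33,closed,NA,H
S0005,F,12.827,R1,S1,43,closed,NA,NA
S0005,F,12.827,R1,S1,34,closed,NA,H
S0005,F,12.827,R1,S1,44,closed,NA,NA
S0005,F,12.827,R1,S1,14,closed,NA,NA
S0005,F,12.827,R1,S1,24,closed,NA,NA
S0005,F,12.827,R1,S1,35,closed,NA,H
S0005,F,12.827,R1,S1,45,closed,NA,NA
S0005,F,12.827,R1,S1,13,open,0.9,NA
S0005,F,12.827,R1,S1,23,open,0.927,NA
S0005,F,12.827,R1,S1,17,open,0.776,NA
S0005,F,12.827,R1,S1,27,open,0.77,NA
S0005,F,12.827,R1,S1,37,open,0.83,F
S0005,F,12.827,R1,S1,47,open,0.764,NA
S0006,M,12.593,R1,S1,31,closed,NA,H
S0006,M,12.593,R1,S1,41,closed,NA,NA
S0006,M,12.593,R1,S1,16,closed,NA,NA
S0006,M,12.593,R1,S1,26,closed,NA,NA
S0006,M,12.593,R1,S1,36,closed,NA,H
S0006,M,12.593,R1,S1,46,closed,NA,NA
S0006,M,12.593,R1,S1,32,closed,NA,H
S0006,M,12.593,R1,S1,42,closed,NA,NA
S0006,M,12.593,R1,S1,11,closed,NA,NA
S0006,M,12.593,R1,S1,21,closed,NA,NA
S0006,M,12.593,R1,S1,12,closed,NA,NA
S0006,M,12.593,R1,S1,22,closed,NA,NA
S0006,M,12.593,R1,S1,33,closed,NA,H
S0006,M,12.593,R1,S1,43,closed,NA,NA
S0006,M,12.593,R1,S1,34,closed,NA,H
S0006,M,12.593,R1,S1,44,closed,NA,NA
S0006,M,12.593,R1,S1,14,open,0.973,NA
S0006,M,12.593,R1,S1,24,open,0.887,NA
S0006,M,12.593,R1,S1,35,open,0.908,G
S0006,M,12.593,R1,S1,45,open,0.871,NA
S0006,M,12.593,R1,S1,13,open,0.719,NA
S0006,M,12.593,R1,S1,23,open,0.743,NA
S0006,M,12.593,R1,S1,17,open,0.63,NA
S0006,M,12.593,R1,S1,27,open,0.554,NA
S0006,M,12.593,R1,S1,37,open,0.584,E
S0006,M,12.593,R1,S1,47,open,0.545,NA
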