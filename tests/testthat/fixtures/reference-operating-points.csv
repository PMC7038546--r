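cohort,algorithm,stratum,tp,fp,fn,tn,sens,spec,ppv,npv,kappa
derivation,A,all,50,97,10,10039,83.3,99.0,34.0,99.9,0.48
derivation,B,all,43,32,17,10104,71.7,99.7,57.3,99.8,0.63
derivation,C,all,58,615,2,9521,96.7,93.9,8.6,100.0,0.15
derivation,D,all,32,9,28,10127,53.3,99.9,78.0,99.7,0.63
derivation,A_and_C,all,49,52,11,10084,81.7,99.5,48.5,99.9,0.61
derivation,A_and_D,all,28,5,32,10131,46.7,100.0,84.8,99.7,0.60
derivation,B_and_C,all,42,19,18,10117,70.0,99.8,68.9,99.8,0.69
derivation,B_and_D,all,25,4,35,10132,41.7,100.0,86.2,99.7,0.56
derivation,A_or_C,all,59,660,1,9476,98.3,93.5,8.2,100.0,0.14
derivation,A_or_D,all,54,101,6,10035,90.0,99.0,34.8,99.9,0.50
derivation,B_or_C,all,59,628,1,9508,98.3,93.8,8.6,100.0,0.15
derivation,B_or_D,all,50,37,10,10099,83.3,99.6,57.5,99.9,0.68
derivation,A,<20,23,9,0,26,100.0,74.3,71.9,100.0,0.70
derivation,B,<20,21,5,2,30,91.3,85.7,80.8,93.8,0.75
derivation,C,<20,23,13,0,22,100.0,62.9,63.9,100.0,0.57
derivation,D,<20,16,3,7,32,69.6,91.4,84.2,82.1,0.63
derivation,A_and_C,<20,23,8,0,27,100.0,77.1,74.2,100.0,0.73
derivation,A_and_D,<20,16,2,7,33,69.6,94.3,88.9,82.5,0.66
derivation,B_and_C,<20,21,5,2,30,91.3,85.7,80.8,93.8,0.75
derivation,B_and_D,<20,15,2,8,33,65.2,94.3,88.2,80.5,0.62
derivation,A_or_C,<20,23,14,0,21,100.0,60.0,62.2,100.0,0.54
derivation,A_or_D,<20,23,10,0,25,100.0,71.4,69.7,100.0,0.66
derivation,B_or_C,<20,23,13,0,22,100.0,62.9,63.9,100.0,0.57
derivation,B_or_D,<20,22,6,1,29,95.7,82.9,78.6,96.7,0.76
derivation,A,20-39,21,53,5,700,80.8,93.0,28.4,99.3,0.39
derivation,B,20-39,19,16,7,737,73.1,97.9,54.3,99.1,0.61
derivation,C,20-39,25,80,1,673,96.2,89.4,23.8,99.9,0.35
derivation,D,20-39,13,3,13,750,50.0,99.6,81.3,98.3,0.61
derivation,A_and_C,20-39,20,23,6,730,76.9,96.9,46.5,99.2,0.56
derivation,A_and_D,20-39,10,1,16,752,38.5,99.9,90.9,97.9,0.53
derivation,B_and_C,20-39,18,8,8,745,69.2,98.9,69.2,98.9,0.68
derivation,B_and_D,20-39,10,1,16,752,38.5,99.9,90.9,97.9,0.53
derivation,A_or_C,20-39,26,110,0,643,100.0,85.4,19.1,100.0,0.28
derivation,A_or_D,20-39,24,55,2,698,92.3,92.7,30.4,99.7,0.43
derivation,B_or_C,20-39,26,88,0,665,100.0,88.3,22.8,100.0,0.34
derivation,B_or_D,20-39,22,18,4,735,84.6,97.6,55.0,99.5,0.65
derivation,A,>=40,6,35,5,9313,54.5,99.6,14.6,99.9,0.23
derivation,B,>=40,3,11,8,9337,27.3,99.9,21.4,99.9,0.24
derivation,C,>=40,10,522,1,8826,90.9,94.4,1.9,100.0,0.03
derivation,D,>=40,3,3,8,9345,27.3,100.0,50.0,99.9,0.35
derivation,A_and_C,>=40,6,21,5,9327,54.5,99.8,22.2,99.9,0.31
derivation,A_and_D,>=40,2,2,9,9346,18.2,100.0,50.0,99.9,0.27
derivation,B_and_C,>=40,3,6,8,9342,27.3,99.9,33.3,99.9,0.30
derivation,B_and_D,>=40,0,1,11,9347,0.0,100.0,NA,99.9,0.00
derivation,A_or_C,>=40,10,536,1,8812,90.9,94.3,1.8,100.0,0.03
derivation,A_or_D,>=40,7,36,4,9312,63.6,99.6,16.3,100.0,0.26
derivation,B_or_C,>=40,10,527,1,8821,90.9,94.4,1.9,100.0,0.03
derivation,B_or_D,>=40,6,13,5,9335,54.5,99.9,31.6,99.9,0.40
validation,B_or_C,all,41,280,2,4778,95.3,94.5,12.8,100.0,0.21
validation,B_or_C,<20,14,6,0,21,100.0,77.8,70.0,100.0,0.71
validation,B_or_C,20-39,19,41,2,300,90.5,88.0,31.7,99.3,0.42
validation,B_or_C,>=40,8,233,0,4457,100.0,95.0,3.3,100.0,0.06
validation,B_and_D,all,16,0,27,5058,37.2,100.0,100.0,99.5,0.54
validation,B_and_D,<20,8,0,6,27,57.1,100.0,100.0,81.8,0.64
validation,B_and_D,20-39,6,0,15,341,28.6,100.0,100.0,95.8,0.43
validation,B_and_D,>=40,2,0,6,4690,25.0,100.0,100.0,99.9,0.40
validation,B_and_C,all,28,9,15,5049,65.1,99.8,75.7,99.7,0.70
validation,B_and_C,<20,12,0,2,27,85.7,100.0,100.0,93.1,0.89
validation,B_and_C,20-39,12,7,9,334,57.1,97.9,63.2,97.4,0.58
validation,B_and_C,>=40,4,2,4,4688,50.0,100.0,66.7,99.9,0.57
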