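k,K,n,N,p
0,0,1,5,1.0000000000000000000000000E+0
0,0,2,8,1.0000000000000000000000000E+0
0,0,2,15,1.0000000000000000000000000E+0
0,0,5,8,1.0000000000000000000000000E+0
0,0,5,20,1.0000000000000000000000000E+0
0,0,6,20,1.0000000000000000000000000E+0
0,0,9,15,1.0000000000000000000000000E+0
0,1,8,8,1.0000000000000000000000000E+0
0,1,15,20,1.0000000000000000000000000E+0
0,2,4,8,1.0000000000000000000000000E+0
0,2,15,15,1.0000000000000000000000000E+0
0,2,17,30,1.0000000000000000000000000E+0
0,3,3,5,1.0000000000000000000000000E+0
0,4,5,5,1.0000000000000000000000000E+0
0,4,5,10,1.0000000000000000000000000E+0
0,4,12,15,1.0000000000000000000000000E+0
0,5,1,8,1.0000000000000000000000000E+0
0,7,2,20,1.0000000000000000000000000E+0
0,10,14,15,1.0000000000000000000000000E+0
0,13,26,50,1.0000000000000000000000000E+0
0,16,36,60,1.0000000000000000000000000E+0
0,35,7,50,1.0000000000000000000000000E+0
0,46,4,50,1.0000000000000000000000000E+0
0,53,1,60,1.0000000000000000000000000E+0
1,1,2,30,6.6666666666666666666666667E-2
1,1,3,40,7.5000000000000000000000000E-2
1,1,8,50,1.6000000000000000000000000E-1
1,1,13,15,8.6666666666666666666666667E-1
1,3,2,8,6.4285714285714285714285714E-1
1,3,5,10,9.1666666666666666666666667E-1
1,4,4,8,9.8571428571428571428571429E-1
1,5,2,5,1.0000000000000000000000000E+0
1,6,1,10,6.0000000000000000000000000E-1
1,7,1,10,7.0000000000000000000000000E-1
1,8,5,30,8.1520778072502210433244916E-1
1,10,7,10,1.0000000000000000000000000E+0
1,14,8,20,1.0000000000000000000000000E+0
1,17,5,40,9.4886232386232386232386232E-1
1,18,7,30,9.9961096374889478337754200E-1
1,58,1,60,9.6666666666666666666666667E-1
2,3,2,15,2.8571428571428571428571429E-2
2,3,9,10,1.0000000000000000000000000E+0
2,5,36,40,9.9994528941897362949994529E-1
2,6,12,15,1.0000000000000000000000000E+0
2,8,28,50,9.9050995602078793783287899E-1
2,14,12,20,1.0000000000000000000000000E+0
2,15,7,20,1.0000000000000000000000000E+0
2,30,30,60,9.9999999999999238148913159E-1
2,49,9,60,9.9999944937283044524174266E-1
3,3,3,30,2.4630541871921182266009852E-4
3,3,10,30,2.9556650246305418719211823E-2
3,4,5,10,2.6190476190476190476190476E-1
3,4,9,15,4.6153846153846153846153846E-1
3,5,7,15,4.2657342657342657342657343E-1
3,5,38,60,7.4605493863237872589129164E-1
3,6,21,30,9.5083996463306808134394341E-1
3,7,16,50,3.9641425487863970750187216E-1
4,4,4,10,4.7619047619047619047619048E-3
4,5,6,8,6.4285714285714285714285714E-1
4,6,4,15,1.0989010989010989010989011E-2
4,11,7,30,2.0035366931918656056587091E-1
4,24,6,30,9.2460949012673150604185087E-1
4,29,10,40,9.9849654908078956815599181E-1
4,35,11,50,9.9878990640690564554678527E-1
5,5,5,60,1.8309947867916430468339171E-7
5,8,5,8,1.0000000000000000000000000E+0
6,14,10,20,9.2956656346749226006191950E-1
7,7,50,60,2.5862923429751077479398867E-1
8,48,12,60,9.4918426793788522964490008E-1
10,20,25,60,2.5778057418547877085351661E-1
11,37,26,40,1.0000000000000000000000000E+0
13,15,31,50,1.8041474327453256020374448E-2
13,22,28,40,9.7990259447434085921293930E-1
14,24,39,40,1.0000000000000000000000000E+0
14,26,15,60,6.3181448371522468781074337E-6
16,23,29,40,7.9870565354436322178257662E-1
17,24,18,50,5.0590109328754253904290023E-7
27,55,39,60,1.0000000000000000000000000E+0
31,42,46,60,8.7293311690084080039174956E-1
33,58,55,60,1.0000000000000000000000000E+0
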