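strain,a,b,r,mortality,mortality_se,mycosis,mycosis_se,lt50
JHML200710,0.83,5.04,0.94,76.7,3.3,61.1,6.7,6.22
ZTZY200812,-0.45,6.23,0.96,73.3,8.8,63.3,12.0,5.71
WSWH318103,3.35,1.63,0.89,60.0,5.7,33.3,6.7,7.49
MDDMF200908,2.74,2.46,0.92,63.3,6.7,50.0,5.8,6.74
GJDW200804,-0.36,5.87,0.96,73.3,12.0,43.3,6.7,6.38
SLSY200714,2.64,2.48,0.95,66.7,3.3,30.0,15.2,7.78
YYDG200805,2.59,5.24,0.78,100.0,0.0,70.0,10.0,4.27
SZDT200901,1.13,4.63,0.93,80.0,5.8,30.0,5.7,5.79
XDLC200731,-1.61,5.64,0.84,30.0,5.7,10.0,5.7,NA
LLZK200810,-0.99,8.84,0.93,100.0,0.0,60.0,5.7,4.55
JHGS200717,2.34,4.58,0.92,96.6,3.3,73.3,3.3,4.65
MDXZ200803,-1.58,11.89,0.95,100.0,0.0,53.3,14.5,3.49
FQMD200805,0.38,9.09,0.89,100.0,0.0,43.3,12.0,3.73
SZBLT201010,-0.27,9.55,0.95,100.0,0.0,86.7,8.8,3.78
SZCY201010,1.65,6.59,0.87,100.0,0.0,80.0,15.2,3.95
MS200810,3.24,2.02,0.99,60.0,5.7,33.3,6.6,5.96
SDSC200925,3.23,2.29,0.99,70.0,5.7,36.7,8.8,5.24
SZLQ200902,3.66,1.67,0.97,63.3,3.3,30.0,5.7,6.08
XSBN200920,-0.28,10.22,0.94,100.0,0.0,86.7,6.7,3.69
LQ200917,3.75,1.43,0.96,53.3,8.8,26.7,6.7,6.85
SZKS200901,3.46,2.08,0.98,66.7,6.7,30.0,5.7,5.13
LPLX200813,3.39,1.64,0.92,50.0,5.7,30.0,5.7,7.47
SB200807,3.58,1.47,0.97,53.3,6.6,40.0,5.7,6.78
FQMY200805,3.72,1.79,0.96,70.0,5.7,36.6,6.7,5.56
HNQLZ200714,3.19,2.37,0.99,63.3,8.8,33.3,7.1,5.57
JDBT200715,3.62,2.29,0.97,80.0,5.7,43.3,6.7,4.90
NJGLX200805,3.22,2.42,0.99,70.0,3.3,36.6,3.3,5.21
LCDH200913,1.03,4.75,0.94,66.7,6.7,43.3,8.8,5.94
PPDB201006,3.09,2.66,0.99,86.7,3.3,53.3,3.3,5.24
LPJL200901,2.78,2.49,0.97,50.0,5.7,30.0,5.7,7.54
CNKJ200805,1.32,4.53,0.92,70.0,10.0,36.6,8.8,5.57
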