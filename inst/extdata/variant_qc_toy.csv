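variant_id,chrom,pos,sample_id,gq,dp,fs,vaf,context
v01,chr1,1000,S1,99,100,0,0.4,ACGTACGTACGTACGTACGTA
v01,chr1,1000,S2,99,100,0,0.4,ACGTACGTACGTACGTACGTA
v01,chr1,1000,S3,99,100,0,0.4,ACGTACGTACGTACGTACGTA
v02,chr1,2000,S1,19,100,0,0.4,ACGTACGTACGTACGTACGTA
v02,chr1,2000,S2,19,100,0,0.4,ACGTACGTACGTACGTACGTA
v02,chr1,2000,S3,19,100,0,0.4,ACGTACGTACGTACGTACGTA
v03,chr1,3000,S1,20,100,0,0.4,ACGTACGTACGTACGTACGTA
v03,chr1,3000,S2,20,100,0,0.4,ACGTACGTACGTACGTACGTA
v03,chr1,3000,S3,20,100,0,0.4,ACGTACGTACGTACGTACGTA
v04,chr1,4000,S1,99,4,0,0.4,ACGTACGTACGTACGTACGTA
v04,chr1,4000,S2,99,4,0,0.4,ACGTACGTACGTACGTACGTA
v04,chr1,4000,S3,99,4,0,0.4,ACGTACGTACGTACGTACGTA
v05,chr1,5000,S1,99,100,0,0.4,ACGTACGTACGTACGTACGTA
v05,chr1,5000,S2,99,100,0,0.4,ACGTACGTACGTACGTACGTA
v05,chr1,5000,S3,99,100,0,0.4,ACGTACGTACGTACGTACGTA
v06,chr1,6000,S1,99,100,45,0.4,ACGTACGTACGTACGTACGTA
v06,chr1,6000,S2,99,100,45,0.4,ACGTACGTACGTACGTACGTA
v06,chr1,6000,S3,99,100,45,0.4,ACGTACGTACGTACGTACGTA
v07,chr1,7000,S1,99,100,40,0.4,ACGTACGTACGTACGTACGTA
v07,chr1,7000,S2,99,100,40,0.4,ACGTACGTACGTACGTACGTA
v07,chr1,7000,S3,99,100,40,0.4,ACGTACGTACGTACGTACGTA
v08,chr1,8000,S1,99,100,39.5,0.4,ACGTACGTACGTACGTACGTA
v08,chr1,8000,S2,99,100,39.5,0.4,ACGTACGTACGTACGTACGTA
v08,chr1,8000,S3,99,100,39.5,0.4,ACGTACGTACGTACGTACGTA
v09,chr1,9000,S1,15,3,50,0.4,ACGTACGTACGTACGTACGTA
v09,chr1,9000,S2,15,3,50,0.4,ACGTACGTACGTACGTACGTA
v09,chr1,9000,S3,15,3,50,0.4,ACGTACGTACGTACGTACGTA
v10,chr1,10000,S1,NA,100,0,0.4,ACGTACGTACGTACGTACGTA
v10,chr1,10000,S2,NA,100,0,0.4,ACGTACGTACGTACGTACGTA
v10,chr1,10000,S3,NA,100,0,0.4,ACGTACGTACGTACGTACGTA
v11,chr1,11000,S1,99,100,0,0.4,ACGTACGTAAAAAGTACGTAC
v11,chr1,11000,S2,99,100,0,0.4,ACGTACGTAAAAAGTACGTAC
v11,chr1,11000,S3,99,100,0,0.4,ACGTACGTAAAAAGTACGTAC
v12,chr1,12000,S1,99,100,0,0.4,ACGTACGTAAAAGTACGTACG
v12,chr1,12000,S2,99,100,0,0.4,ACGTACGTAAAAGTACGTACG
v12,chr1,12000,S3,99,100,0,0.4,ACGTACGTAAAAGTACGTACG
v13,chr1,13000,S1,99,100,0,0.4,CAAAAACGTACGTACGTACGT
v13,chr1,13000,S2,99,100,0,0.4,CAAAAACGTACGTACGTACGT
v13,chr1,13000,S3,99,100,0,0.4,CAAAAACGTACGTACGTACGT
v14,chr1,14000,S1,99,100,0,0.4,AAAAACGTACGTACGTACGTA
v14,chr1,14000,S2,99,100,0,0.4,AAAAACGTACGTACGTACGTA
v14,chr1,14000,S3,99,100,0,0.4,AAAAACGTACGTACGTACGTA
v15,chr1,15000,S1,99,60,0,0.4,ACGTACGTACGTACGTACGTA
v15,chr1,15000,S2,99,60,0,0.4,ACGTACGTACGTACGTACGTA
v15,chr1,15000,S3,99,10,0,0.4,ACGTACGTACGTACGTACGTA
v16,chr1,16000,S1,99,100,0,0.05,ACGTACGTACGTACGTACGTA
v16,chr1,16000,S2,99,100,0,0.08,ACGTACGTACGTACGTACGTA
v16,chr1,16000,S3,99,100,0,0.09,ACGTACGTACGTACGTACGTA
v17,chr1,17000,S1,99,40,0,0.4,ACGTACGTACGTACGTACGTA
v17,chr1,17000,S2,99,40,0,0.4,ACGTACGTACGTACGTACGTA
v17,chr1,17000,S3,99,60,0,0.4,ACGTACGTACGTACGTACGTA
v18,chr1,18000,S1,99,60,0,0.4,ACGTACGTACGTACGTACGTA
v18,chr1,18000,S2,99,55,0,0.4,ACGTACGTACGTACGTACGTA
v18,chr1,18000,S3,99,50,0,0.4,ACGTACGTACGTACGTACGTA
v19,chr1,19000,S1,99,100,0,0.4,ACGTACGTACGTACGTACGTA
v19,chr1,19000,S2,99,90,0,0.4,ACGTACGTACGTACGTACGTA
v19,chr1,19000,S3,99,80,0,0.4,ACGTACGTACGTACGTACGTA
v20,chr1,20000,S1,99,50,0,0.1,ACGTACGTACGTACGTACGTA
v20,chr1,20000,S2,99,50,0,0.05,ACGTACGTACGTACGTACGTA
v20,chr1,20000,S3,99,15,0,0.05,ACGTACGTACGTACGTACGTA
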