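locus,group,forward,reverse,a,size_min,size_max,he,ho,fis,pid,pid_sib
Disu033,highly_recommended,TCTGGATACCTGAGGCTTGAC,ACTGGCATCACTTCTTTCCC,2,152,164,0.53,0.00,1.00,0.41,0.63
Disu098,highly_recommended,GCTAGGAGAGGGTGTTGGAC,TGGTAGCCTTGCCTCTTTCC,4,98,126,0.78,0.20,0.76,0.14,0.44
Disu100,highly_recommended,TGTGGACTTGTCATATATGGGC,TTCATCCATGCTGTCACAAATG,2,120,122,0.36,0.40,-0.14,0.51,0.72
Disu201,highly_recommended,TGGAGAGAATTTCAGACATGGG,CTAGCCCAAGATCCATTGGC,2,156,158,0.53,0.00,1.00,0.39,0.61
Disu261,highly_recommended,AAACCATACGCGGGAGAAGG,GAAGGGAAGATCATGCAGGAG,2,150,166,0.60,0.33,0.50,0.38,0.59
Disu393,highly_recommended,AGTGAGCAAGGGAATGTGTG,GGGTGCTGTCTCTTGATTGG,2,155,157,0.36,0.40,-0.14,0.51,0.72
Disu448,highly_recommended,CAGGTTTCGTTACTGCAGGAC,TCTGGTGACCTGAGATGCAC,2,154,156,0.20,0.20,NA,0.69,0.83
Disu476,highly_recommended,AAACAGGGAAACAAGGTGCG,GACTGCGCCCTTTCTGTTAG,3,162,174,0.60,0.80,-0.39,0.29,0.55
Disu487,highly_recommended,TATCATGTCACAAGCACGCG,GTCTTCTTCACGACAGCACC,2,148,160,0.20,0.20,NA,0.69,0.83
Disu783,highly_recommended,CCTTGCCTTGCCTTCAATCC,CCATCCTTTCTCCTACACAGAC,3,126,134,0.51,0.60,-0.20,0.34,0.61
Disu847,highly_recommended,AAAGTCGCCTCTCACACACC,TCAGAGCCTCCTTGTAAGCG,2,138,140,0.20,0.20,NA,0.69,0.83
Disu050,recommended,CTCCCACATTCAGCAAACTTTC,CCAGGCAGTGATGACTCTAC,3,160,166,0.51,0.20,0.64,0.34,0.61
Disu071,recommended,TTGAGATGCATTGCCGTGG,CCATGGTTTCTGCATCGTGG,3,168,172,0.73,0.33,0.60,0.23,0.50
Disu076,recommended,TTCCAGCCGCTCTTATGACC,TCATGTGCTTATTGGCCATCTG,2,125,129,0.53,0.00,1.00,0.41,0.63
Disu127,recommended,CCACCACCACCATGCATAG,CATTTGCTCCCATGCTGAAG,2,162,164,0.36,0.00,1.00,0.51,0.72
Disu138,recommended,GGGACACATGACTCCTCTTATC,CCACTCCACCTTATACTACCAC,2,167,169,0.53,0.00,1.00,0.41,0.63
Disu149,recommended,GAGCGTGCATGGTAGTTTCC,GGTTCTCATAGCAGACGGAG,4,160,168,0.73,1.00,-0.43,0.18,0.47
Disu151,recommended,CATTGTGCTCGCTACGCAG,CTAGGTGTCAAGAGCCAGGG,2,135,137,0.36,0.00,1.00,0.51,0.72
Disu480,recommended,CCTGCCTTCTAGTCCTGTGG,AGCAAGCAGGATCAGGAAGG,2,112,116,0.47,0.20,0.60,0.42,0.65
Disu501,recommended,TGGCCACATCTTCAGCATTAAG,GCACCTAACACAGTTACAGGC,2,155,157,0.47,0.60,-0.33,0.42,0.65
Disu542,recommended,AAACTACAGGCACGTACAGC,TTGAGAGATGAGGTGCGGTC,2,128,130,0.20,0.20,NA,0.69,0.83
Disu545,recommended,TGTTGTCCAAGCTGTGTCTG,TGGCAGCTGGTACCTAACAG,2,148,150,0.20,0.20,NA,0.69,0.83
Disu556,recommended,GCCAATTAAATCTACCTGCCAC,GCCAAGACTCAAACCCAGG,2,168,174,0.25,0.25,NA,0.63,0.80
Disu582,recommended,TCTGTGGTGGTAGCTGTGAC,TGGCACAGAGACACCCATG,2,144,152,0.36,0.00,1.00,0.51,0.72
Disu593,recommended,CCACGTCCCAGGTCAAGAG,AGCTGTTCCTGGTGGCTC,3,164,166,0.56,0.20,0.67,0.38,0.59
Disu733,recommended,TGGCACAGAGACACCCATG,TCTGTGGTGGTAGCTGTGAC,2,151,159,0.36,0.00,1.00,0.51,0.72
Disu748,recommended,CCTTGATTGGTGGGTTCCC,AGAGAGAGCGCACGTGTG,3,106,116,0.64,0.80,-0.28,0.26,0.53
Disu269,not_recommended,CAAGACCACACCTGCTTGTC,ACTCACTCATCACCCAGCC,3,115,152,0.60,0.33,0.50,0.30,0.58
Disu863,not_recommended,GAAGCTGTATGTCCGGATGC,GCTAAACAGACCTTCCTCAGAG,2,162,166,0.36,0.40,-0.14,0.51,0.72
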