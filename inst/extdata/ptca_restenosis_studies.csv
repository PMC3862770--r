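study_id,year,ethnicity,ethnicity_label,intervention,followup_months,restenosis_definition,n_case_II,n_case_ID,n_case_DD,n_ctrl_II,n_ctrl_ID,n_ctrl_DD,a_case_I,a_case_D,a_ctrl_I,a_ctrl_D,cases_total,controls_total,mean_age,pct_male,quality,ace_inhibitor_stratum
Ohishi,1993,Asian,Japanese,balloon,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,32,50,NA,NA,High,unstratified
Beohar,1995,Caucasian,American,balloon,3,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,64,25,63.9,NA,High,unstratified
vanBockxmeer,1995,Caucasian,Australian,balloon,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,88,119,57.0,82.1,High,unstratified
Kamitani,1995,Asian,Japanese,balloon,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,38,52,52.0,100,High,unstratified
Kaski,1996,Caucasian,Spanish,balloon,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,35,34,58.0,82.6,Median,unstratified
Tsukada,1997,Asian,Japanese,balloon,3,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,25,71,60.0,NA,Median,unstratified
Hamon,1998,Caucasian,French,balloon,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,116,155,60.0,84.5,High,unstratified
Yoshida,1999,Asian,Japanese,balloon,62.4,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,47,123,58.2,NA,High,unstratified
Okamura,1999,Asian,Japanese,balloon,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,19,27,60.0,86.6,High,unstratified
Volzke,2000,Caucasian,German,balloon,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,160,351,60.6,75.9,High,unstratified
Zee,2001,Caucasian,Spanish,balloon,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,342,437,58.9,89.2,High,unstratified
Samani,1995,Caucasian,British,balloon,4,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,110,123,NA,83.3,High,unstratified
Amant,1997,Caucasian,French,stent,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,59,99,60.0,80.1,High,unstratified
Gensini,1999,Caucasian,Italian,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,27,130,NA,NA,Median,unstratified
Guarda,1999,Other,Chilean,stent,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,22,26,NA,NA,Median,unstratified
Gurlek,2000,Caucasian,Turkish,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,51,107,53.0,84.8,High,unstratified
Koch,2000,Caucasian,German,stent,12,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,513,1043,62.9,78.8,High,unstratified
Jorgensen,2001,Caucasian,Dane,stent,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,49,320,59.0,79.4,High,unstratified
Taniguchi,2001,Asian,Japanese,stent,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,26,41,65.2,74.6,Median,unstratified
Ferrari,2002,Caucasian,German,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,39,115,61.0,77.3,High,unstratified
Ryu,2002,Asian,Korean,stent,6,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,64,191,59.5,74.8,High,unstratified
Gomma,2002,Caucasian,British,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,60,144,59.4,75.6,High,unstratified
Qu,2002,Asian,Chinese,stent,3,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,43,85,68.0,84.4,Median,unstratified
Okumura,2002,Asian,Japanese,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,16,76,64.3,79.3,Median,unstratified
Ribichini,2003,Caucasian,Italian,stent,6.3,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,271,727,61.0,82.2,High,unstratified
Guo,2005,Asian,Chinese,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,30,73,70.0,NA,Median,unstratified
Wang2005a,2005,Asian,Chinese,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,62,40,62.0,88.2,Median,unstratified
Guneri,2005,Caucasian,Turkish,stent,9,diameter stenosis >=70%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,48,48,59.6,62.8,High,unstratified
Wang2005b,2005,Asian,Chinese,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,58,139,NA,NA,Median,unstratified
Ujiie,2006,Asian,Japanese,stent,7,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,15,60,66.9,78.6,Median,unstratified
Gao,2006,Asian,Chinese,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,102,247,NA,NA,Median,unstratified
Wijpkema,2006,Caucasian,Dutch,stent,9,diameter stenosis >50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,316,2572,62.0,70.9,High,unstratified
Lv,2012,Asian,Chinese,stent,6,diameter stenosis >=50%,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,81,315,58.8,89.4,High,unstratified
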