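female_id,male_id,ejaculate,semen_group,shipped,n_laid,n_eggs,n_fertile_ai,n_parthenote,n_hatched_ai,first_fertile_day,last_fertile_day,parthenote_days,fertility_pct_printed,hatchability_pct_printed,duration_printed
854,320,E1,fresh,none,43,41,11,1,9,14,121,4,26.8,22.0,107
101,381,E2,fresh,none,30,30,17,0,15,8,111,,56.7,50.0,103
283,381,E4,fresh,none,32,30,20,0,18,15,116,,66.7,60.0,101
268,381,E5,fresh,none,36,36,21,0,14,6,103,,58.3,38.9,97
793,395,E1,cold24,FL-TN,27,23,12,0,12,10,79,,52.2,52.2,69
036,320,E3,fresh,none,34,32,12,0,11,12,63,,37.5,34.4,51
581,381,E1,fresh,none,32,31,4,0,3,8,63,,12.9,9.7,55
512,381,E3,fresh,none,12,11,3,0,3,11,60,,27.3,27.3,49
034,381,E3,fresh,none,19,19,5,0,5,16,60,,26.3,26.3,44
370,2969,E1,cold24,NJ-CA,18,18,2,0,2,19,49,,11.1,11.1,30
785,381,E4,fresh,none,26,24,1,0,1,10,10,,4.2,4.2,1
376,381,E1,cold48,none,14,14,1,0,1,44,44,,7.1,7.1,1
307,320,E1,fresh,none,39,39,1,2,1,13,13,87;91,7.7,2.6,1
626,395,E1,cold24,FL-TN,19,5,1,0,1,59,59,,20.0,20.0,1
583,395,E1,cold24,FL-TN,22,11,1,0,1,60,60,,9.1,9.1,1
063,381,E2,fresh,none,16,16,0,0,0,NA,NA,,0,0,NA
775,381,E3,fresh,none,16,16,0,0,0,NA,NA,,0,0,NA
551,381,E5,fresh,none,6,6,0,0,0,NA,NA,,0,0,NA
065,320,E2,fresh,none,26,26,0,0,0,NA,NA,,0,0,NA
095,320,E2,fresh,none,2,2,0,0,0,NA,NA,,0,0,NA
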