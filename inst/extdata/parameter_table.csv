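category,name,arm,value,low,high,distribution,unit_size,source
survival,os_family,tislelizumab,gengamma,,,fixed,,model_fit
survival,os_mu,tislelizumab,2.569464,,,fixed,,model_fit
survival,os_sigma,tislelizumab,1.402937,,,fixed,,model_fit
survival,os_q,tislelizumab,-0.645479,,,fixed,,model_fit
survival,os_family,sorafenib,lognormal,,,fixed,,model_fit
survival,os_meanlog,sorafenib,2.78300,,,fixed,,model_fit
survival,os_sdlog,sorafenib,1.18198,,,fixed,,model_fit
survival,pfs_family,tislelizumab,gengamma,,,fixed,,model_fit
survival,pfs_mu,tislelizumab,0.74281,,,fixed,,model_fit
survival,pfs_sigma,tislelizumab,0.76369,,,fixed,,model_fit
survival,pfs_q,tislelizumab,-1.74938,,,fixed,,model_fit
survival,pfs_family,sorafenib,gengamma,,,fixed,,model_fit
survival,pfs_mu,sorafenib,0.887573,,,fixed,,model_fit
survival,pfs_sigma,sorafenib,0.671562,,,fixed,,model_fit
survival,pfs_q,sorafenib,-1.684204,,,fixed,,model_fit
cost_drug,tislelizumab,,192.85,154.28,231.42,gamma,100,yaozh_bid_price
cost_drug,sorafenib,,3.19,2.55,3.83,gamma,200,yaozh_bid_price
cost_drug,camrelizumab,,360.73,288.58,432.88,gamma,200,yaozh_bid_price
cost_drug,oxaliplatin,,47.13,37.70,56.56,gamma,50,yaozh_bid_price
cost_drug,calcium_folinate,,13.72,10.98,16.46,gamma,100,yaozh_bid_price
cost_drug,fluorouracil,,4.06,3.25,4.87,gamma,250,yaozh_bid_price
cost_followup,followup,,84.77,67.82,101.72,gamma,,literature
cost_ae,ast_increased,,59,47.20,70.80,gamma,,literature
cost_ae,alt_increased,,59,47.20,70.80,gamma,,literature
cost_ae,bilirubin_increased,,124.90,99.92,149.88,gamma,,literature
cost_ae,rash_pruritus,,7,5.60,8.40,gamma,,literature
cost_ae,platelet_decreased,,332.15,265.72,398.58,gamma,,literature
cost_ae,fatigue,,3,2.40,3.60,gamma,,literature
cost_ae,diarrhea,,88.38,70.70,106.06,gamma,,literature
cost_ae,decreased_appetite,,107.38,85.90,128.86,gamma,,literature
cost_ae,weight_decreased,,75.20,60.16,90.24,gamma,,literature
cost_ae,hypertension,,64.01,51.21,76.81,gamma,,literature
cost_ae,alopecia,,183,146.40,219.60,gamma,,literature
cost_ae,ppe_syndrome,,145.65,116.52,174.78,gamma,,literature
risk_ae,ast_increased,tislelizumab,0.231,0.2079,0.2541,beta,,trial
risk_ae,alt_increased,tislelizumab,0.166,0.1494,0.1826,beta,,trial
risk_ae,bilirubin_increased,tislelizumab,0.124,0.1116,0.1364,beta,,trial
risk_ae,rash_pruritus,tislelizumab,0.205,0.1845,0.2255,beta,,trial
risk_ae,platelet_decreased,tislelizumab,0.071,0.0639,0.0781,beta,,trial
risk_ae,fatigue,tislelizumab,0.062,0.0558,0.0682,beta,,trial
risk_ae,diarrhea,tislelizumab,0.056,0.0504,0.0616,beta,,trial
risk_ae,decreased_appetite,tislelizumab,0.050,0.0450,0.0550,beta,,trial
risk_ae,weight_decreased,tislelizumab,0.033,0.0297,0.0363,beta,,trial
risk_ae,hypertension,tislelizumab,0.027,0.0243,0.0297,beta,,trial
risk_ae,alopecia,tislelizumab,0.003,0.0027,0.0033,beta,,trial
risk_ae,ppe_syndrome,tislelizumab,0.003,0.0027,0.0033,beta,,trial
risk_ae,ast_increased,sorafenib,0.287,0.2583,0.3157,beta,,trial
risk_ae,alt_increased,sorafenib,0.250,0.2250,0.2750,beta,,trial
risk_ae,bilirubin_increased,sorafenib,0.207,0.1863,0.2277,beta,,trial
risk_ae,rash_pruritus,sorafenib,0.216,0.1944,0.2376,beta,,trial
risk_ae,platelet_decreased,sorafenib,0.151,0.1359,0.1661,beta,,trial
risk_ae,fatigue,sorafenib,0.105,0.0945,0.1155,beta,,trial
risk_ae,diarrhea,sorafenib,0.392,0.3528,0.4312,beta,,trial
risk_ae,decreased_appetite,sorafenib,0.120,0.1080,0.1320,beta,,trial
risk_ae,weight_decreased,sorafenib,0.111,0.0999,0.1221,beta,,trial
risk_ae,hypertension,sorafenib,0.247,0.2223,0.2717,beta,,trial
risk_ae,alopecia,sorafenib,0.225,0.2025,0.2475,beta,,trial
risk_ae,ppe_syndrome,sorafenib,0.627,0.5643,0.6897,beta,,trial
utility,utility_pfs,,0.76,0.76,0.80,beta,,literature
utility,utility_pd,,0.68,0.60,0.68,beta,,literature
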