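"parameter_ref","target","family","p1","p2","p3","p4","reconstructed"
"p_paper","probability","beta",5,95,NA,NA,TRUE
"p_followup","probability","beta",35,65,NA,NA,TRUE
"p_fail","probability","beta",32.5,67.5,NA,NA,TRUE
"p_birads","probability","beta",4.5,95.5,NA,NA,TRUE
"p_high_tc","probability","beta",1.47,98.53,NA,NA,TRUE
"p_mod_tc","probability","beta",8.46,91.54,NA,NA,TRUE
"p_high_vbd","probability","beta",5,95,NA,NA,TRUE
"p_mod_vbd","probability","beta",11.2,88.8,NA,NA,TRUE
"p_high_snp","probability","beta",7.4,92.6,NA,NA,TRUE
"p_mod_snp","probability","beta",10.5,89.5,NA,NA,TRUE
"p_attend_high","probability","beta",74.29,25.71,NA,NA,TRUE
"p_attend_mod","probability","beta",73.12,26.88,NA,NA,TRUE
"inv_staff","quantity","uniform",2,8,NA,NA,TRUE
"q_entry","quantity","uniform",12.5,30,NA,NA,TRUE
"q_phone","quantity","uniform",2.5,7.5,NA,NA,TRUE
"vol_followup","quantity","uniform",5,7.5,NA,NA,TRUE
"letter_retrieve","quantity","uniform",5,10,NA,NA,TRUE
"organize_appt","quantity","uniform",1.5,3,NA,NA,TRUE
"risk_pack","quantity","uniform",5,30,NA,NA,TRUE
"saliva_collection","quantity","uniform",2,5,NA,NA,TRUE
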