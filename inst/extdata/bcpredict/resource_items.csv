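"id","stage","description","quantity","unit_cost_ref","settings","printed_cost_gbp","assumed","vans_per_trust","weeks_between_moves","screens_per_week"
"inv_print","invitation","Printing study invitation and information, 7 sheets",7,"sheet","trial",NA,FALSE,NA,NA,NA
"inv_staff","invitation","Printing letter and filling envelope, 5 min",5,"admin_hour","trial",NA,FALSE,NA,NA,NA
"inv_post","invitation","Posting the invitation, 1 stamp",1,"stamp","trial",NA,FALSE,NA,NA,NA
"q_print","questionnaire","Printing paper survey, 4 sheets",4,"sheet","trial,nhs",NA,FALSE,NA,NA,NA
"q_post","questionnaire","Return postage for paper survey, 1 stamp",1,"stamp","trial,nhs",NA,FALSE,NA,NA,NA
"q_entry","questionnaire","Manual transfer of paper survey to CRA system, 21.25 min",21.25,"admin_hour","trial,nhs",NA,FALSE,NA,NA,NA
"q_phone","questionnaire","Telephone follow-up of unclear paper survey, 5 min (assumed)",5,"admin_hour","trial,nhs",NA,TRUE,NA,NA,NA
"volpara","density","Automated breast-density measurement, 1 per woman",1,"volpara_fee","trial,nhs",NA,FALSE,NA,NA,NA
"vol_followup","density_implementation","Research fellow follows up failed image transfer, 6.25 min",6.25,"fellow_hour","trial",NA,FALSE,NA,NA,NA
"birads_read","density_implementation","Consultant manual BI-RADS read after transfer failure, 1 min",1,"consultant_hour","trial",NA,FALSE,NA,NA,NA
"aerial","density_implementation","Aerial uninstall/reinstall amortised over screens",NA,"van_move","trial",NA,FALSE,2,3,580
"saliva_collection","snp","Nurse collects saliva sample, 3.5 min",3.5,"nurse_hour","trial,nhs",NA,FALSE,NA,NA,NA
"snp_staff","snp","Staff time running SNP test, full-batch per-sample share",38.39,"snp_staff_hour","trial,nhs",25.25,FALSE,NA,NA,NA
"snp_consumables","snp","SNP consumables incl. chips, full-batch per-sample share",1,"snp_consumables_full","trial,nhs",NA,FALSE,NA,NA,NA
"letter_retrieve","risk_letter","Retrieving risk data from CRA and transferring to collator, 7.5 min",7.5,"admin_hour","trial",NA,FALSE,NA,NA,NA
"letter_print","risk_letter","Printing risk letter, 2 sheets",2,"sheet","trial,nhs",NA,FALSE,NA,NA,NA
"letter_fill","risk_letter","Printing letter and filling envelope, 2 min",2,"admin_hour","trial,nhs",NA,FALSE,NA,NA,NA
"letter_post","risk_letter","Posting the risk letter, 1 stamp",1,"stamp","trial,nhs",NA,FALSE,NA,NA,NA
"organize_appt","consultation","Organising risk appointment, 2.25 min",2.25,"admin_hour","trial,nhs",NA,FALSE,NA,NA,NA
"risk_pack","consultation","Collating risk pack for clinician, 17.5 min",17.5,"admin_hour","trial",NA,FALSE,NA,NA,NA
"consult_high","consultation","Consultant-led high-risk consultation, 30 min",30,"consultant_hour","trial",NA,FALSE,NA,NA,NA
"consult_mod","consultation","Consultant-led moderate-risk consultation, 20 min",20,"consultant_hour","trial",NA,FALSE,NA,NA,NA
"consult_high_nhs","consultation","Nurse-led high-risk consultation, 30 min",30,"nurse_hour","nhs",NA,FALSE,NA,NA,NA
"consult_mod_nhs","consultation","Nurse-led moderate-risk consultation, 20 min",20,"nurse_hour","nhs",NA,FALSE,NA,NA,NA
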