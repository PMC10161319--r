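"id","description","value_gbp","unit","source","price_year"
"sheet","Printing, per sheet of paper",0.12,"per_sheet","published stationery cost, inflated to 2021",2021
"stamp","Second-class stamp",0.66,"per_stamp","2021 UK second-class stamp",2021
"admin_hour","Administrator (grade 4 scientific staff proxy), per hour",35,"per_hour","PSSRU 2021",2021
"fellow_hour","Research fellow (grade 7 scientific staff proxy), per hour",62,"per_hour","PSSRU 2021",2021
"consultant_hour","Medical consultant, per hour",123,"per_hour","PSSRU 2021",2021
"nurse_hour","Band 5 nurse, per hour",41,"per_hour","PSSRU 2021",2021
"snp_staff_hour","Grade 5 scientific staff running SNP test, per hour",41,"per_hour","PSSRU 2021",2021
"volpara_fee","Automated breast-density measurement, per image",1.15,"per_measurement","supplier communication",2021
"van_move","Uninstall/reinstall internet aerial, per van move",500,"per_move","supplier communication",2021
"snp_consumables_full","SNP test consumables incl. array chips, per-sample share, full batch",51.73,"per_item","published full-batch aggregate",2021
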