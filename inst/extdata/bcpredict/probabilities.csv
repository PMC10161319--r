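"id","value","description","source"
"p_paper",0.05,"Completes the risk questionnaire on paper rather than online","study interviews"
"p_followup",0.35,"Paper survey unclear, needs telephone follow-up","study interviews"
"p_fail",0.325,"Mammography image fails to transfer for density measurement","study interviews"
"p_birads",0.045,"Failed image needs manual BI-RADS reading","study interviews"
"p_high_tc",0.0147,"Predicted high risk, questionnaire-only strategy","published risk distribution"
"p_mod_tc",0.0846,"Predicted moderate risk, questionnaire-only strategy","published risk distribution"
"p_high_vbd",0.05,"Predicted high risk, questionnaire + breast density","published risk distribution"
"p_mod_vbd",0.112,"Predicted moderate risk, questionnaire + breast density","published risk distribution"
"p_high_snp",0.074,"Predicted high risk, questionnaire + density + SNP","published risk distribution"
"p_mod_snp",0.105,"Predicted moderate risk, questionnaire + density + SNP","published risk distribution"
"p_attend_high",0.7429,"High-risk woman organises a risk appointment","published uptake"
"p_attend_mod",0.7312,"Moderate-risk woman organises a risk appointment","published uptake"
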