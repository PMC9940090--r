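"drug","sample","Na_IC50","Na_h","NaL_IC50","NaL_h","to_IC50","to_h","CaL_IC50","CaL_h","Kr_IC50","Kr_h","Ks_IC50","Ks_h","K1_IC50","K1_h"
"synthA_herg",0,,,,,,,,,"1.1808465235103323","0.84853547354392422",,,,
"synthA_herg",1,,,,,,,,,"1.0445374270787677","0.77325725924991118",,,,
"synthA_herg",2,,,,,,,,,"1.0105869081782","0.83169026519667311",,,,
"synthA_herg",3,,,,,,,,,"1.6200685213449373","0.96835196796479428",,,,
"synthA_herg",4,,,,,,,,,"1.1103727530844614","0.67112765752926373",,,,
"synthA_herg",5,,,,,,,,,"1.2237733130330635","0.88983157724753026",,,,
"synthA_herg",6,,,,,,,,,"0.90268050249682952","0.901519078695312",,,,
"synthA_herg",7,,,,,,,,,"0.99058261592668195","0.95914458568728622",,,,
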