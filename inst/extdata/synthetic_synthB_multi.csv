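"drug","sample","Na_IC50","Na_h","NaL_IC50","NaL_h","to_IC50","to_h","CaL_IC50","CaL_h","Kr_IC50","Kr_h","Ks_IC50","Ks_h","K1_IC50","K1_h"
"synthB_multi",0,,,"1237.5924022435797","1.0769121181083583",,,"509.04706656251847","1.0745522623220372","296.26275762919579","0.84208886951468465",,,,
"synthB_multi",1,,,"1512.3722892635087","0.82448965636630434",,,"558.96376314759539","1.2952501581761082","243.36160346698273","0.65667453329322767",,,,
"synthB_multi",2,,,"1301.7521119174869","0.89461112853385605",,,"539.57713138617521","1.1573911125742125","338.48693542782132","0.83203752081801685",,,,
"synthB_multi",3,,,"1824.5323208578468","1.1278584371305029",,,"589.75663678103547","1.1185410747997124","362.74930063437409","0.8414089684488435",,,,
"synthB_multi",4,,,"1126.1930861902006","0.91900467096103777",,,"532.69626881376939","1.0006589325908428","429.9822110866736","0.84455715737785553",,,,
"synthB_multi",5,,,"1356.1360493907907","0.84796962322839597",,,"877.50257786454438","0.97106783897082438","395.40881179252182","0.76233661184875201",,,,
"synthB_multi",6,,,"1461.2652993113359","1.0235187133716228",,,"635.42209563544748","1.1072747147275579","417.6262461436865","0.87196282364648969",,,,
"synthB_multi",7,,,"1401.5269586422028","1.0490423738736916",,,"631.94099311609557","1.0192286323205655","422.78055077665073","0.7520215228022451",,,,
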