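"drug","sample","Na_IC50","Na_h","NaL_IC50","NaL_h","to_IC50","to_h","CaL_IC50","CaL_h","Kr_IC50","Kr_h","Ks_IC50","Ks_h","K1_IC50","K1_h"
"synthC_cal",0,"37219.468003334419","0.92745661323226114",,,,,"279.58385388794494","0.97962485671209532","10184.862808111231","0.85604413314780348",,,,
"synthC_cal",1,"32721.073976928365","1.0253080574618281",,,,,"315.77528230613507","0.91600338757712985","14207.694870423868","1.0839505481712401",,,,
"synthC_cal",2,"28927.262322940311","0.91594459330955558",,,,,"203.978344646799","0.8825769925138307","14533.925082177811","0.90198658573524149",,,,
"synthC_cal",3,"30231.365260748385","0.81450575275827874",,,,,"262.57750046781371","0.88722519010963097","10611.756136391801","0.67202703424083465",,,,
"synthC_cal",4,"22363.972215108966","1.0853808878324664",,,,,"288.34904739647158","0.91774206465458064","10961.762963321458","0.89618715339828814",,,,
"synthC_cal",5,"40712.953431499278","0.89502926740680588",,,,,"285.61337428873173","1.0649704510002735","12276.792844371465","0.99995999408277769",,,,
"synthC_cal",6,"36817.196581350785","0.98672894093383168",,,,,"301.85094255386849","1.2596215797516093","10402.486059412659","0.88530045997722473",,,,
"synthC_cal",7,"27145.90575327642","0.96407845721925467",,,,,"260.57526582322464","1.0537395588231693","13427.186068961437","0.71836084326038696",,,,
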