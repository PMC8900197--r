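"sample_id","reference","truth","scm_call","bf_call"
"icm001","ICM","aneuploid","euploid","euploid"
"icm002","ICM","aneuploid","euploid","euploid"
"icm003","ICM","aneuploid","aneuploid","euploid"
"icm004","ICM","aneuploid","aneuploid","euploid"
"icm005","ICM","aneuploid","aneuploid","aneuploid"
"icm006","ICM","aneuploid","aneuploid","aneuploid"
"icm007","ICM","aneuploid","aneuploid","aneuploid"
"icm008","ICM","aneuploid","aneuploid","aneuploid"
"icm009","ICM","aneuploid","aneuploid","aneuploid"
"icm010","ICM","aneuploid","aneuploid","aneuploid"
"icm011","ICM","aneuploid","aneuploid","aneuploid"
"icm012","ICM","aneuploid","aneuploid","aneuploid"
"icm013","ICM","aneuploid","aneuploid","aneuploid"
"icm014","ICM","aneuploid","aneuploid","aneuploid"
"icm015","ICM","aneuploid","aneuploid","aneuploid"
"icm016","ICM","aneuploid","aneuploid","aneuploid"
"icm017","ICM","aneuploid","aneuploid","aneuploid"
"icm018","ICM","aneuploid","aneuploid","aneuploid"
"icm019","ICM","aneuploid","aneuploid","aneuploid"
"icm020","ICM","aneuploid","aneuploid","aneuploid"
"icm021","ICM","aneuploid","aneuploid","aneuploid"
"icm022","ICM","aneuploid","aneuploid","aneuploid"
"icm023","ICM","aneuploid","aneuploid","aneuploid"
"icm024","ICM","aneuploid","aneuploid","aneuploid"
"icm025","ICM","aneuploid","aneuploid","aneuploid"
"icm026","ICM","aneuploid","aneuploid","aneuploid"
"icm027","ICM","aneuploid","aneuploid","aneuploid"
"icm028","ICM","aneuploid","aneuploid","aneuploid"
"icm029","ICM","aneuploid","aneuploid","aneuploid"
"icm030","ICM","euploid","aneuploid","aneuploid"
"icm031","ICM","euploid","aneuploid","aneuploid"
"icm032","ICM","euploid","aneuploid","aneuploid"
"icm033","ICM","euploid","aneuploid","aneuploid"
"icm034","ICM","euploid","aneuploid","aneuploid"
"icm035","ICM","euploid","aneuploid","aneuploid"
"icm036","ICM","euploid","aneuploid","aneuploid"
"icm037","ICM","euploid","aneuploid","aneuploid"
"icm038","ICM","euploid","aneuploid","aneuploid"
"icm039","ICM","euploid","euploid","aneuploid"
"icm040","ICM","euploid","euploid","aneuploid"
"icm041","ICM","euploid","euploid","aneuploid"
"icm042","ICM","euploid","euploid","aneuploid"
"icm043","ICM","euploid","euploid","aneuploid"
"icm044","ICM","euploid","euploid","aneuploid"
"icm045","ICM","euploid","euploid","aneuploid"
"icm046","ICM","euploid","euploid","aneuploid"
"icm047","ICM","euploid","euploid","aneuploid"
"icm048","ICM","euploid","euploid","aneuploid"
"icm049","ICM","euploid","euploid","aneuploid"
"icm050","ICM","euploid","euploid","aneuploid"
"icm051","ICM","euploid","euploid","aneuploid"
"icm052","ICM","euploid","euploid","aneuploid"
"icm053","ICM","euploid","euploid","aneuploid"
"icm054","ICM","euploid","euploid","euploid"
"icm055","ICM","euploid","euploid","euploid"
"icm056","ICM","euploid","euploid","euploid"
"icm057","ICM","euploid","euploid","euploid"
"icm058","ICM","euploid","euploid","euploid"
"icm059","ICM","euploid","euploid","euploid"
"icm060","ICM","euploid","euploid","euploid"
"icm061","ICM","euploid","euploid","euploid"
"icm062","ICM","euploid","euploid","euploid"
"icm063","ICM","euploid","euploid","euploid"
"icm064","ICM","euploid","euploid","euploid"
"icm065","ICM","euploid","euploid","euploid"
"icm066","ICM","euploid","euploid","euploid"
"icm067","ICM","euploid","euploid","euploid"
"icm068","ICM","euploid","euploid","euploid"
"icm069","ICM","euploid","euploid","euploid"
"icm070","ICM","euploid","euploid","euploid"
"icm071","ICM","euploid","euploid","euploid"
"icm072","ICM","euploid","euploid","euploid"
"icm073","ICM","euploid","euploid","euploid"
"icm074","ICM","euploid","euploid","euploid"
"icm075","ICM","euploid","euploid","euploid"
"icm076","ICM","euploid","euploid","euploid"
"icm077","ICM","euploid","euploid","euploid"
"icm078","ICM","euploid","euploid","euploid"
"icm079","ICM","euploid","euploid","euploid"
"icm080","ICM","euploid","euploid","euploid"
"icm081","ICM","euploid","euploid","euploid"
"icm082","ICM","euploid","euploid","euploid"
"icm083","ICM","euploid","euploid","euploid"
"icm084","ICM","euploid","euploid","euploid"
"icm085","ICM","euploid","euploid","euploid"
"icm086","ICM","euploid","euploid","euploid"
"icm087","ICM","euploid","euploid","euploid"
"icm088","ICM","euploid","euploid","euploid"
"icm089","ICM","euploid","euploid","euploid"
"wb001","WB","aneuploid","euploid","euploid"
"wb002","WB","aneuploid","euploid","euploid"
"wb003","WB","aneuploid","aneuploid","aneuploid"
"wb004","WB","aneuploid","aneuploid","aneuploid"
"wb005","WB","aneuploid","aneuploid","aneuploid"
"wb006","WB","aneuploid","aneuploid","aneuploid"
"wb007","WB","aneuploid","aneuploid","aneuploid"
"wb008","WB","aneuploid","aneuploid","aneuploid"
"wb009","WB","aneuploid","aneuploid","aneuploid"
"wb010","WB","aneuploid","aneuploid","aneuploid"
"wb011","WB","aneuploid","aneuploid","aneuploid"
"wb012","WB","aneuploid","aneuploid","aneuploid"
"wb013","WB","aneuploid","aneuploid","aneuploid"
"wb014","WB","aneuploid","aneuploid","aneuploid"
"wb015","WB","aneuploid","aneuploid","aneuploid"
"wb016","WB","aneuploid","aneuploid","aneuploid"
"wb017","WB","aneuploid","aneuploid","aneuploid"
"wb018","WB","aneuploid","aneuploid","aneuploid"
"wb019","WB","euploid","aneuploid","aneuploid"
"wb020","WB","euploid","aneuploid","aneuploid"
"wb021","WB","euploid","aneuploid","aneuploid"
"wb022","WB","euploid","aneuploid","aneuploid"
"wb023","WB","euploid","aneuploid","aneuploid"
"wb024","WB","euploid","aneuploid","aneuploid"
"wb025","WB","euploid","aneuploid","aneuploid"
"wb026","WB","euploid","aneuploid","aneuploid"
"wb027","WB","euploid","aneuploid","aneuploid"
"wb028","WB","euploid","aneuploid","aneuploid"
"wb029","WB","euploid","aneuploid","aneuploid"
"wb030","WB","euploid","euploid","aneuploid"
"wb031","WB","euploid","euploid","aneuploid"
"wb032","WB","euploid","euploid","aneuploid"
"wb033","WB","euploid","euploid","aneuploid"
"wb034","WB","euploid","euploid","euploid"
"wb035","WB","euploid","euploid","euploid"
"wb036","WB","euploid","euploid","euploid"
"wb037","WB","euploid","euploid","euploid"
"wb038","WB","euploid","euploid","euploid"
"wb039","WB","euploid","euploid","euploid"
"wb040","WB","euploid","euploid","euploid"
"wb041","WB","euploid","euploid","euploid"
"wb042","WB","euploid","euploid","euploid"
"wb043","WB","euploid","euploid","euploid"
"wb044","WB","euploid","euploid","euploid"
"wb045","WB","euploid","euploid","euploid"
"wb046","WB","euploid","euploid","euploid"
"wb047","WB","euploid","euploid","euploid"
"wb048","WB","euploid","euploid","euploid"
"wb049","WB","euploid","euploid","euploid"
"wb050","WB","euploid","euploid","euploid"
"wb051","WB","euploid","euploid","euploid"
"wb052","WB","euploid","euploid","euploid"
"wb053","WB","euploid","euploid","euploid"
"wb054","WB","euploid","euploid","euploid"
"wb055","WB","euploid","euploid","euploid"
"wb056","WB","euploid","euploid","euploid"
"wb057","WB","euploid","euploid","euploid"
"wb058","WB","euploid","euploid","euploid"
"wb059","WB","euploid","euploid","euploid"
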