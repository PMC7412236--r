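"dataset","n_classes"
"Adiac",37
"Beef",5
"CBF",3
"ChlorineCon",3
"CinTorso",4
"Coffee",2
"CricketX",12
"CricketY",12
"CricketZ",12
"DiatomSizeR",4
"ECG200",2
"ECGFiveDays",2
"FaceAll",14
"FaceFour",4
"FacesUCR",14
"FiftyWords",50
"Fish",7
"GunPoint",2
"Haptics",5
"InlineSkate",7
"ItaPowDemand",2
"Lightning2",2
"Lightning7",7
"Mallat",8
"MedicalImg",10
"MoteStrain",2
"NonInThorax1",42
"NonInThorax2",42
"OliveOil",4
"OSULeaf",6
"SonyAIRobot1",2
"SonyAIRobot2",2
"StarLigCurves",3
"SwedishLeaf",15
"Symbols",6
"SynControl",6
"Trace",4
"TwoLeadECG",2
"TwoPatterns",4
"UWaveX",8
"UWaveY",8
"UWaveZ",8
"Wafer",2
"WoSynonyms",25
"Yoga",2
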