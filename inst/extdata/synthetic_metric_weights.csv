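metric,feature_id,point_value
word_order,PH001,1
word_order,PH002,0
word_order,PH003,1
word_order,SP001,0.5
locus_of_marking,PH004,1
locus_of_marking,PH005,0.5
locus_of_marking,PH006,0
fusion,PH007,0.5
fusion,PH008,1
fusion,NS001,0.5
flexivity,PH009,1
flexivity,PH010,0.5
noun_class_gender,PH011,1
noun_class_gender,PH012,1
noun_class_gender,NS002,0
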