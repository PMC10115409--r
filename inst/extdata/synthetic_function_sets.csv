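set_name,feature_id
reflexive,PH013
reflexive,PH014
passive,PH015
passive,SP002
singular_number,PH016
tense,PH017
tense,NS003
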