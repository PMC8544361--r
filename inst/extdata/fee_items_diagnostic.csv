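item_number,description,category,mean_fee,frequency_weight
011,Comprehensive oral examination,Diagnostic,55.2,1
012,Periodic oral examination,Diagnostic,45.85,1
013,Oral examination - limited,Diagnostic,28,1
022,Intraoral periapical or bitewing radiograph - per exposure,Diagnostic,38.8,2
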