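unit_id,jurisdiction,decile,remoteness,pop_65plus
NSW,NSW,5,Unclassified,1205970
Vic,Vic,5,Unclassified,913529
Qld,Qld,5,Unclassified,710213
WA,WA,5,Unclassified,342652
SA,SA,5,Unclassified,303581
Tas,Tas,5,Unclassified,97658
ACT,ACT,5,Unclassified,49018
NT,NT,5,Unclassified,15838
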