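# MAF Variant_Classification vocabulary -> internal enumeration.
# Matching is case-insensitive; terms absent from this table map to "other".
Frame_Shift_Del: frameshift
Frame_Shift_Ins: frameshift
In_Frame_Del: inframe_indel
In_Frame_Ins: inframe_indel
Splice_Site: splice
Splice_Region: splice
Missense_Mutation: missense
Nonsense_Mutation: nonsense
Nonstop_Mutation: nonsense
Silent: synonymous
Synonymous: synonymous
frameshift: frameshift
inframe_indel: inframe_indel
splice: splice
missense: missense
nonsense: nonsense
other: other
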