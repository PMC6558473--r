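label	class
Missense_Mutation	nonsynonymous_SNV
Nonsense_Mutation	stopgain
Nonstop_Mutation	stoploss
Frame_Shift_Del	frameshift_indel
Frame_Shift_Ins	frameshift_indel
In_Frame_Del	inframe_indel
In_Frame_Ins	inframe_indel
Splice_Site	splicing
Silent	silent
Translation_Start_Site	other
Splice_Region	other
3'UTR	other
5'UTR	other
3'Flank	other
5'Flank	other
Intron	other
IGR	other
RNA	other
nonsynonymous SNV	nonsynonymous_SNV
synonymous SNV	silent
stopgain SNV	stopgain
stoploss SNV	stoploss
frameshift deletion	frameshift_indel
frameshift insertion	frameshift_indel
nonframeshift deletion	inframe_indel
nonframeshift insertion	inframe_indel
nonsynonymous_SNV	nonsynonymous_SNV
frameshift_indel	frameshift_indel
inframe_indel	inframe_indel
stopgain	stopgain
stoploss	stoploss
splicing	splicing
silent	silent
other	other
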