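gene	chr	start	end	annotation	de_flag
ABHD2	chr15	89113724	89116521	C-term|canonicalMet	FALSE
ANKRD12	chr18	9182381	9221999	C-term|canonicalMet|conservedStructure	TRUE
ARAP2	chr4	36228581	36229645	C-term|canonicalMet|lackingDomain	TRUE
CLNS1A	chr11	77619605	77625818	canonicalSTOP|conservedStructure|internalMet	FALSE
CPSF6	chr12	69251128	69262562	canonicalSTOP|conservedStructure|internalMet	FALSE
CSNK1G3	chr5	123545416	123557564	C-term|canonicalMet	FALSE
FBXW7	chr4	152411302	152412529	C-term|canonicalMet	FALSE
HIPK3	chr11	33286412	33287511	C-term|canonicalMet|conservedStructure	TRUE
KLHL8	chr4	87195323	87195690	C-term|canonicalMet	FALSE
MGA	chr15	41668827	41669958	C-term|canonicalMet|lackingDomain	FALSE
NCOA2	chr8	70213902	70216764	C-term|canonicalMet|novelDomainStructure	TRUE
OMA1	chr1	58506059	58539310	C-term|canonicalMet|conservedStructure	FALSE
PCMTD1	chr8	51860844	51861246	C-term|canonicalMet|conservedStructure	FALSE
PDE3B	chr11	14771936	14789242	C-term|internalMet	FALSE
RELL1	chr4	37631384	37638504	canonicalSTOP|internalMet	FALSE
RNF13	chr3	149846010	149921227	C-term|canonicalMet|conservedStructure	TRUE
RNF220	chr1	44411980	44412722	C-term|canonicalMet	FALSE
RSRC1	chr3	158122102	158123991	C-term|canonicalMet	FALSE
SATB1	chr3	18378169	18420991	C-term|canonicalMet|lackingDomain	TRUE
SHOC2	chr10	110964124	110985765	lackingDomain	FALSE
SLC38A1	chr12	46229152	46243314	C-term|canonicalMet|conservedStructure	FALSE
SLC8A1	chr2	40428472	40430304	C-term|canonicalMet|conservedStructure	TRUE
XPO1	chr2	61522610	61533903	C-term|canonicalMet|conservedStructure	TRUE
ZBTB44	chr11	130260855	130261929	C-term|canonicalMet|lackingDomain	FALSE
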