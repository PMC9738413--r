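drug	therapy	pan_sensitive	pan_resistant
afatinib	targeted	CDT1, INCENP	IL4I1, LRP1, FAM156B, DCUN1D4, ESPN, PTPRJ, NMNAT2
alectinib	targeted	CSNK2A3, DYNC1H1, PSME1	UCP3, CDC45, THSD7A, ANKRD52, EIF2A, FAM156B, KRT8, CFAP44
brigatinib	targeted		MYOF, ABHD10, TMTC4
cabozantinib	targeted	CSNK2A3	RNASEL, TMTC4, SMC2, ASB7, CFAP44, IL17RA, ZXDA, THSD7A
carboplatin	systemic		ASB7, RAB1A
cisplatin	systemic	ZNF507, CSNK2A3, WDR17	ARHGAP12, CDC45, ESPN, EIF2A, IL17RA, MYOF, TMTC4, NMNAT2, PTPRJ, KRT8
crizotinib	targeted	RFC4, CSNK2A3, MCM2, MDN1, CDT1, INCENP	LRP1, IL17RA
dabrafenib	targeted	FBLN7, MAP2, CTNNB1, RNF128, CSNK2A3, WDR17, ZNF507	FAM156B, SLC39A8, SMC2, KRT8, NMNAT2
dacomitinib	targeted	CDT1	MAP3K7, DCUN1D4, LRP1, THOC5, FAM156B, ANKRD52, THSD7A
docetaxel	systemic	RFC4, ABCC5, FBLN7, MAP2	SLC39A8, IL17RA, KRT8, RAB1A, THSD7A, DCUN1D4, MYOF, NMNAT2
erlotinib	targeted	CSNK2A3, PSMB6, TGFB2	FAM156B, ASB7, TMTC4, NMNAT2
etoposide	systemic	PSMB3, CDT1, DYNC1H1, ZNF507	ESPN, NMNAT2, ZNF324B, IL17RA
gefitinib	targeted	BRMS1L, CCNA2, CDT1, INCENP	IL4I1, ABHD10, FAM156B, MAP3K7, DCUN1D4, NMNAT2, PTPRJ, KRT8
gemcitabine	systemic	MDGA1, MDN1, ZNF507, WDR17	KRT8, ANKRD52, ASB7, RAB1A, FAM156B, IL17RA, DCUN1D4, IL4I1, LRP1, NMNAT2
lorlatinib	targeted	MDN1, PSMB6	ANKRD52, ESPN, RAB1A
osimertinib	targeted	ABCC5, MDGA1, TCF20, MAP2, PSMB6	ASB7, DCUN1D4, THSD7A
paclitaxel	systemic	INCENP, CDT1, MCM2, TCF20	RAB1A, THOC5, ASB7, IL17RA, NMNAT2, KRT8, LRP1, SLC39A8, THSD7A, UCP3
pemetrexed	systemic	MCM2, CCNA2	EIF2A, IL17RA, MYOF, THSD7A, ZXDA, ARHGAP12, LRP1
trametinib	targeted	CTNNB1	RNASEL, IL17RA, ANKRD52, FAM156B, AP2S1, ARHGAP12, SRRM2, UCP3, ZXDA, TMTC4, DCUN1D4, NCOR1, RAB1A
vemurafenib	targeted		RNASE L, IL17RA
vinorelbine	systemic	ABCC5, DYNC1H1, IRX1, TCF20	RAB1A, SLC39A8, KRT8, DCUN1D4, PTPRJ, IL17RA, MYOF, NMNAT2
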