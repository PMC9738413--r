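drug	therapy	pan_sensitive	pan_resistant
afatinib	targeted	DDX42, RFX7, FAT1, CREBBP	IL4I1, KRT8, CDCA4, DIXDC1
alectinib	targeted	DDX42, ZNF507	CCNA2, KIF14, CDK1, DAG1, ANKRD52, MAP3K7
brigatinib	targeted	FAT1, PTPRJ, PSME1	TEN1, MAP3K7, FBLN7, CDK1
cabozantinib	targeted	KANSL1, CHL1, TGFB2	TJP1_G3V1L9, BPTF_E9PE19, NSD1, SYNE2_Q8WXH0_5, RDX, ANKRD52
carboplatin	systemic		TJP1_G3V1L9
cisplatin	systemic	MYCL, DDX42, BRMS1L, KANSL1, ZNF507	BPTF_E9PE19, FBLN7, DIP2B, MYOF, CDK1
crizotinib	targeted	FAM208A, TOMM7, KANSL1	DAG1
dabrafenib	targeted	BRMS1L, RBBP4, ZNF507, DDX42, KANSL1	RDX, ANKRD52, DIP2B, CDK1, DAG1, IL17RA
dacomitinib	targeted	PSME1, DDX42, GREB1, RBBP4	MAP2_P11137_4, KRT8, CDC45, CDCA4, IL4I1
docetaxel	systemic	TOMM7, CREBBP, TCF20, DDX42, FAM208A, THOC5, ZNF507	DYNC1H1, MYOF
erlotinib	targeted	RFX7, THOC5, CREBBP	KIF14, CDCA4
etoposide	systemic	CHL1, FAT1	
gefitinib	targeted	DDX42, CREBBP, TCF20, CHL1	CDCA4, IL4I1
gemcitabine	systemic	DDX42, CREBBP, ZNF507, RBBP4, TOMM7	DIP2B, ANKRD52, CDK1, MAP2_P11137_4, IL17RA, SLC39A8
lorlatinib	targeted	ASB7, PSME1, PIR	CCNA2, MYOF, CDK1, CDC45
osimertinib	targeted		CDCA4, EIF4G3_B1AN89, IL4I1, ADARB1, CDC45
paclitaxel	systemic	CHL1, THOC5, ZNF507, UCHL3	SLC39A8, DIXDC1, DIP2B, MYOF, IL17RA
pemetrexed	systemic	THOC5	BPTF_E9PE19, RDX, DYNC1H1
trametinib	targeted	CHL1, PSME1, TMTC4, JOSD2, PTPRJ, RPS19	RDX, DAG1, IL17RA, MAP3K7
vemurafenib	targeted	FAM208A	KRT8
vinorelbine	systemic	TCF20, UCHL3, RBBP4, THOC5, ZNF507	TJP1_G3V1L9
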