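name	sequence	amidated	pyroglu	published_mass	type
Lom-PK-1	DSGDEWPQQPFVPRL	TRUE	FALSE	1768.8533	
Lom-PK-3	GAVPAAQFSPRL	TRUE	FALSE	1211.6775	
Lom-PK-4	EGDFTPRL	TRUE	FALSE	932.4716	
Lom-PK-5	RQQPFVPRL	TRUE	FALSE	1138.6724	
Lom-PK-8	QQPFVPRL	TRUE	TRUE	965.5447	
Lom-PK-10	ESAEQGGGVSAWQGGEPQQEEQVLAGPFVPRL	TRUE	FALSE	3335.6169	
Lom-PKL-1	QDGDKGISKLKKTSSLFPHPRI	TRUE	TRUE	2433.3491	
Lom-PVK-1	AAGLFQFPRV	TRUE	FALSE	1103.6239	
Lom-PVK-2	RGLLAFPRV	TRUE	FALSE	1026.645	
Lom-PVK-3	DGGQPAAPLWFGPRV	TRUE	FALSE	1565.8102	
Lom-PK-11	KGLVASARV	TRUE	FALSE	898.5712	
Lom-DH-1	SDAQVDDMLWFGPRP	TRUE	FALSE	1731.8038	I
Lom-DH-2	AQPPGLWFGPRV	TRUE	FALSE	1322.7247	I
Lom-DH-3	AAKQPALWFGPRV	TRUE	FALSE	1438.8197	I
Lom-DH-4	GAKHPGLWFGPRF	TRUE	FALSE	1467.7887	I
Lom-DH-5	SHPEPGMWFGPRV	TRUE	FALSE	1494.719	II
Lom-DH-6	HPEPGMWFGPRV	TRUE	FALSE	1407.687	II
Lom-DH-7	NQPEPGTWFGARI	TRUE	FALSE	1470.7368	IV
Lom-DH-8	SQAEPGVWFGARI	TRUE	FALSE	1415.731	V
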