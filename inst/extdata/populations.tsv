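individual	population	latitude	longitude
CAM_01	CAM	5.2916532	9.4208524
CAM_02	CAM	5.2916532	9.4208524
CAM_03	CAM	5.2916532	9.4208524
CAM_04	CAM	5.2916532	9.4208524
CAM_05	CAM	5.2916532	9.4208524
CAM_06	CAM	5.2916532	9.4208524
CAM_07	CAM	5.2916532	9.4208524
CAM_08	CAM	5.2916532	9.4208524
CAM_09	CAM	5.2916532	9.4208524
CAM_10	CAM	5.2916532	9.4208524
CAM_11	CAM	5.2916532	9.4208524
CAM_12	CAM	5.2916532	9.4208524
CAM_13	CAM	5.2916532	9.4208524
CAM_14	CAM	5.2916532	9.4208524
CAM_15	CAM	5.2916532	9.4208524
GHN_01	GHN	6.1104472	-0.2673795
GHN_02	GHN	6.1104472	-0.2673795
GHN_03	GHN	6.1104472	-0.2673795
GHN_04	GHN	6.1104472	-0.2673795
GHN_05	GHN	6.1104472	-0.2673795
GHN_06	GHN	6.1104472	-0.2673795
GHN_07	GHN	6.1104472	-0.2673795
GHN_08	GHN	6.1104472	-0.2673795
GHN_09	GHN	6.1104472	-0.2673795
GHN_10	GHN	6.1104472	-0.2673795
GHN_11	GHN	6.1104472	-0.2673795
GHN_12	GHN	6.1104472	-0.2673795
GHN_13	GHN	6.1104472	-0.2673795
GHN_14	GHN	6.1104472	-0.2673795
GHN_15	GHN	6.1104472	-0.2673795
SR_01	SR	0.1172028	103.6054083
SR_02	SR	0.1172028	103.6054083
SR_03	SR	0.1172028	103.6054083
SR_04	SR	0.1172028	103.6054083
SR_05	SR	0.1172028	103.6054083
SR_06	SR	0.1172028	103.6054083
SR_07	SR	0.1172028	103.6054083
SR_08	SR	0.1172028	103.6054083
SR_09	SR	0.1172028	103.6054083
SR_10	SR	0.1172028	103.6054083
SR_11	SR	0.1172028	103.6054083
SR_12	SR	0.1172028	103.6054083
SR_13	SR	0.1172028	103.6054083
SR_14	SR	0.1172028	103.6054083
SR_15	SR	0.1172028	103.6054083
NR_01	NR	2.8770875	103.7287832
NR_02	NR	2.8770875	103.7287832
NR_03	NR	2.8770875	103.7287832
NR_04	NR	2.8770875	103.7287832
NR_05	NR	2.8770875	103.7287832
NR_06	NR	2.8770875	103.7287832
NR_07	NR	2.8770875	103.7287832
NR_08	NR	2.8770875	103.7287832
NR_09	NR	2.8770875	103.7287832
NR_10	NR	2.8770875	103.7287832
NR_11	NR	2.8770875	103.7287832
NR_12	NR	2.8770875	103.7287832
NR_13	NR	2.8770875	103.7287832
NR_14	NR	2.8770875	103.7287832
NR_15	NR	2.8770875	103.7287832
CWK_01	CWK	-2.4329821	112.000172
CWK_02	CWK	-2.4329821	112.000172
CWK_03	CWK	-2.4329821	112.000172
CWK_04	CWK	-2.4329821	112.000172
CWK_05	CWK	-2.4329821	112.000172
CWK_06	CWK	-2.4329821	112.000172
CWK_07	CWK	-2.4329821	112.000172
CWK_08	CWK	-2.4329821	112.000172
CWK_09	CWK	-2.4329821	112.000172
CWK_10	CWK	-2.4329821	112.000172
CWK_11	CWK	-2.4329821	112.000172
CWK_12	CWK	-2.4329821	112.000172
CWK_13	CWK	-2.4329821	112.000172
CWK_14	CWK	-2.4329821	112.000172
CWK_15	CWK	-2.4329821	112.000172
SK_01	SK	3.6063617	115.5897206
SK_02	SK	3.6063617	115.5897206
SK_03	SK	3.6063617	115.5897206
SK_04	SK	3.6063617	115.5897206
SK_05	SK	3.6063617	115.5897206
SK_06	SK	3.6063617	115.5897206
SK_07	SK	3.6063617	115.5897206
SK_08	SK	3.6063617	115.5897206
SK_09	SK	3.6063617	115.5897206
SK_10	SK	3.6063617	115.5897206
SK_11	SK	3.6063617	115.5897206
SK_12	SK	3.6063617	115.5897206
SK_13	SK	3.6063617	115.5897206
SK_14	SK	3.6063617	115.5897206
SK_15	SK	3.6063617	115.5897206
NPM_01	NPM	5.3678468	100.7063803
NPM_02	NPM	5.3678468	100.7063803
NPM_03	NPM	5.3678468	100.7063803
NPM_04	NPM	5.3678468	100.7063803
NPM_05	NPM	5.3678468	100.7063803
NPM_06	NPM	5.3678468	100.7063803
NPM_07	NPM	5.3678468	100.7063803
NPM_08	NPM	5.3678468	100.7063803
NPM_09	NPM	5.3678468	100.7063803
NPM_10	NPM	5.3678468	100.7063803
NPM_11	NPM	5.3678468	100.7063803
NPM_12	NPM	5.3678468	100.7063803
NPM_13	NPM	5.3678468	100.7063803
NPM_14	NPM	5.3678468	100.7063803
NPM_15	NPM	5.3678468	100.7063803
CPM_01	CPM	3.4032204	101.4013073
CPM_02	CPM	3.4032204	101.4013073
CPM_03	CPM	3.4032204	101.4013073
CPM_04	CPM	3.4032204	101.4013073
CPM_05	CPM	3.4032204	101.4013073
CPM_06	CPM	3.4032204	101.4013073
CPM_07	CPM	3.4032204	101.4013073
CPM_08	CPM	3.4032204	101.4013073
CPM_09	CPM	3.4032204	101.4013073
CPM_10	CPM	3.4032204	101.4013073
CPM_11	CPM	3.4032204	101.4013073
CPM_12	CPM	3.4032204	101.4013073
CPM_13	CPM	3.4032204	101.4013073
CPM_14	CPM	3.4032204	101.4013073
CPM_15	CPM	3.4032204	101.4013073
SPM_01	SPM	2.0160711	102.9960109
SPM_02	SPM	2.0160711	102.9960109
SPM_03	SPM	2.0160711	102.9960109
SPM_04	SPM	2.0160711	102.9960109
SPM_05	SPM	2.0160711	102.9960109
SPM_06	SPM	2.0160711	102.9960109
SPM_07	SPM	2.0160711	102.9960109
SPM_08	SPM	2.0160711	102.9960109
SPM_09	SPM	2.0160711	102.9960109
SPM_10	SPM	2.0160711	102.9960109
SPM_11	SPM	2.0160711	102.9960109
SPM_12	SPM	2.0160711	102.9960109
SPM_13	SPM	2.0160711	102.9960109
SPM_14	SPM	2.0160711	102.9960109
SPM_15	SPM	2.0160711	102.9960109
SS_01	SS	1.8433571	111.2101607
SS_02	SS	1.8433571	111.2101607
SS_03	SS	1.8433571	111.2101607
SS_04	SS	1.8433571	111.2101607
SS_05	SS	1.8433571	111.2101607
SS_06	SS	1.8433571	111.2101607
SS_07	SS	1.8433571	111.2101607
SS_08	SS	1.8433571	111.2101607
SS_09	SS	1.8433571	111.2101607
SS_10	SS	1.8433571	111.2101607
SS_11	SS	1.8433571	111.2101607
SS_12	SS	1.8433571	111.2101607
SS_13	SS	1.8433571	111.2101607
SS_14	SS	1.8433571	111.2101607
SS_15	SS	1.8433571	111.2101607
NS_01	NS	3.375704	113.4109915
NS_02	NS	3.375704	113.4109915
NS_03	NS	3.375704	113.4109915
NS_04	NS	3.375704	113.4109915
NS_05	NS	3.375704	113.4109915
NS_06	NS	3.375704	113.4109915
NS_07	NS	3.375704	113.4109915
NS_08	NS	3.375704	113.4109915
NS_09	NS	3.375704	113.4109915
NS_10	NS	3.375704	113.4109915
NS_11	NS	3.375704	113.4109915
NS_12	NS	3.375704	113.4109915
NS_13	NS	3.375704	113.4109915
NS_14	NS	3.375704	113.4109915
NS_15	NS	3.375704	113.4109915
SBH_01	SBH	4.406925	117.8172309
SBH_02	SBH	4.406925	117.8172309
SBH_03	SBH	4.406925	117.8172309
SBH_04	SBH	4.406925	117.8172309
SBH_05	SBH	4.406925	117.8172309
SBH_06	SBH	4.406925	117.8172309
SBH_07	SBH	4.406925	117.8172309
SBH_08	SBH	4.406925	117.8172309
SBH_09	SBH	4.406925	117.8172309
SBH_10	SBH	4.406925	117.8172309
SBH_11	SBH	4.406925	117.8172309
SBH_12	SBH	4.406925	117.8172309
SBH_13	SBH	4.406925	117.8172309
SBH_14	SBH	4.406925	117.8172309
SBH_15	SBH	4.406925	117.8172309
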