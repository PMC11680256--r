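"setting","year","indicator","dimension","dimension_type","subgroup","estimate","se","population","subgroup_order","favourable","setting_average","income_group","group_of_interest"
"synthland_01",,"dtp3","wealth","ordered","q1",63.75,1.38772520694841,0.2,1,TRUE,,,
"synthland_01",,"dtp3","wealth","ordered","q2",66.4166666666667,1.36335769809796,0.2,2,TRUE,,,
"synthland_01",,"dtp3","wealth","ordered","q3",74.1666666666667,1.26358360171321,0.2,3,TRUE,,,
"synthland_01",,"dtp3","wealth","ordered","q4",76,1.2328828005938,0.2,4,TRUE,,,
"synthland_01",,"dtp3","wealth","ordered","q5",77.75,1.20067255458486,0.2,5,TRUE,,,
"synthland_02",,"dtp3","wealth","ordered","q1",65.3333333333333,1.37382946809544,0.2,1,TRUE,,,
"synthland_02",,"dtp3","wealth","ordered","q2",67.4166666666667,1.3529781108793,0.2,2,TRUE,,,
"synthland_02",,"dtp3","wealth","ordered","q3",72.6666666666667,1.28654000527974,0.2,3,TRUE,,,
"synthland_02",,"dtp3","wealth","ordered","q4",76.5,1.22397916648936,0.2,4,TRUE,,,
"synthland_02",,"dtp3","wealth","ordered","q5",78.75,1.1809027267307,0.2,5,TRUE,,,
"synthland_03",,"dtp3","region","nonordered","region_1",79.8888888888889,1.33610309024568,0.16,,TRUE,,,
"synthland_03",,"dtp3","region","nonordered","region_2",77.3333333333333,1.39558386383179,0.16,,TRUE,,,
"synthland_03",,"dtp3","region","nonordered","region_3",78.8888888888889,1.36032353127459,0.16,,TRUE,,,
"synthland_03",,"dtp3","region","nonordered","region_4",77.8888888888889,1.38331721940141,0.16,,TRUE,,,
"synthland_03",,"dtp3","region","nonordered","region_5",78.4444444444445,1.37069065326244,0.16,,TRUE,,,
"synthland_03",,"dtp3","region","nonordered","region_6",77.4444444444444,1.39315886831801,0.16,,TRUE,,,
"synthland_03",,"dtp3","region","nonordered","region_7",42.7777777777778,1.64918818620719,0.04,,TRUE,,,
"synthland_04",,"dtp3","region","nonordered","region_1",77.5555555555556,1.39071978087475,0.16,,TRUE,,,
"synthland_04",,"dtp3","region","nonordered","region_2",80,1.33333333333333,0.16,,TRUE,,,
"synthland_04",,"dtp3","region","nonordered","region_3",79.1111111111111,1.35504949064049,0.16,,TRUE,,,
"synthland_04",,"dtp3","region","nonordered","region_4",79.4444444444444,1.34702334029025,0.16,,TRUE,,,
"synthland_04",,"dtp3","region","nonordered","region_5",77.7777777777778,1.3857990321385,0.16,,TRUE,,,
"synthland_04",,"dtp3","region","nonordered","region_6",76.4444444444444,1.41448512738133,0.16,,TRUE,,,
"synthland_04",,"dtp3","region","nonordered","region_7",42.8888888888889,1.64972458939378,0.04,,TRUE,,,
"synthland_05",,"dtp3","residence","binary","rural",72.16,0.896422757408579,0.5,,TRUE,,,"urban"
"synthland_05",,"dtp3","residence","binary","urban",75.72,0.857550371698363,0.5,,TRUE,,,"urban"
"synthland_06",,"dtp3","residence","binary","rural",73.44,0.8833043416626,0.5,,TRUE,,,"urban"
"synthland_06",,"dtp3","residence","binary","urban",75.8,0.856588582692999,0.5,,TRUE,,,"urban"
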