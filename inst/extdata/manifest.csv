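"name","value","ci_low","ci_high","family","source"
"risk.recurrent_vte.m0_3",0.0171,0.012,0.022,"beta","published"
"risk.recurrent_vte.m3_6",0.0048,0.0022,0.0075,"beta","published"
"risk.recurrent_vte.m6_9",0.0048,1e-04,0.011,"beta","published"
"risk.recurrent_vte.m9_12",0.0059,7e-04,0.011,"beta","published"
"risk.recurrent_vte.m12_15",0.0012,0,0.0035,"beta","published"
"risk.recurrent_vte.m15_18",0.0036,0,0.0076,"beta","published"
"risk.major_bleed.m0_3",0.0041,0.0017,0.0065,"beta","published"
"risk.major_bleed.m3_6",0.0015,0,0.003,"beta","published"
"risk.major_bleed.m6_999",0.0024,0,0.0057,"beta","published"
"risk.crnm_bleed.m0_3",0.0265,0.0204,0.0326,"beta","published"
"risk.crnm_bleed.m3_6",0.012,0.0078,0.0161,"beta","published"
"risk.crnm_bleed.m6_999",0.03,0.0182,0.0412,"beta","published"
"risk.ae_disc.m0_6",0.0487,0.0405,0.0568,"beta","published"
"risk.ae_disc.m6_999",0.0667,0.0498,0.0835,"beta","published"
"rr.initial_lmwh_vka.recurrent_vte",1.18,0.83,1.66,"lognormal","published"
"rr.initial_lmwh_vka.major_bleed",3.26,1.84,5.79,"lognormal","published"
"rr.initial_lmwh_vka.crnm_bleed",2.09,1.66,2.63,"lognormal","published"
"rr.initial_lmwh_vka.ae_disc",1.07,0.85,1.35,"lognormal","published"
"rr.extended_placebo.recurrent_vte",5.33,3.02,9.4,"lognormal","published"
"rr.extended_placebo.crnm_bleed",0.78,0.43,1.4,"lognormal","published"
"rr.extended_vka.recurrent_vte",0.42,0.16,1.06,"lognormal","published"
"rr.extended_vka.major_bleed",7.7,1.09,76.4,"lognormal","published"
"rr.extended_vka.crnm_bleed",3.84,1.55,9.38,"lognormal","published"
"rr.extended_vka.ae_disc",1.33,0.75,1.87,"lognormal","published"
"abs.extended_placebo.major_bleed",0.0048,0.000881159420289855,0.026063768115942,"lognormal","derived"
"split.on.vte_death",0.2154,0.144730601218175,0.286069398781825,"beta","derived"
"split.on.pe",0.3769,0.293593988958964,0.460206011041036,"beta","derived"
"split.on.dvt",0.4077,0.32322550245848,0.49217449754152,"beta","derived"
"split.off.vte_death",0.1188,0.055698330591508,0.181901669408492,"beta","derived"
"split.off.pe",0.2475,0.163334087119018,0.331665912880982,"beta","derived"
"split.off.dvt",0.6337,0.539737254628325,0.727662745371675,"beta","derived"
"split.major_bleed.fatal",0.1346,0.0677060183466405,0.20149398165336,"beta","derived"
"split.major_bleed.ic_of_nonfatal",0.1397,0.0717515998233954,0.207648400176605,"beta","derived"
"longterm.cteph_probability",0.0125,3e-04,0.0246,"beta","published"
"longterm.pts_cumulative",0.081,0.059,0.104,"beta","published"
"cost.apix_daily_initial",4.39,3.073,5.707,"gamma","derived"
"cost.apix_daily_extended",2.2,1.54,2.86,"gamma","derived"
"cost.lmwh_vka_daily_initial",9.02,6.314,11.726,"gamma","derived"
"cost.vka_daily",0.015,0.0105,0.0195,"gamma","derived"
"cost.lmwh_education",17.5,12.25,22.75,"gamma","published"
"cost.lmwh_admin_daily",9.04,6.33,11.75,"gamma","published"
"cost.monitor_first_cycle",122.18,85.526,158.834,"gamma","derived"
"cost.monitor_subsequent_cycle",58.72,41.104,76.336,"gamma","derived"
"cost.dvt",389.72,272.8,506.64,"gamma","published"
"cost.pe",1340.41,938.29,1742.54,"gamma","published"
"cost.ic_acute",2760.57,2017.43,3252.62,"gamma","published"
"cost.ic_maintenance",4387.76,3685.78,5107.61,"gamma","published"
"cost.ic_long_term_cycle",672.53,473.01,894.93,"gamma","published"
"cost.cteph_acute",1888.23,1379.02,2225.48,"gamma","published"
"cost.cteph_long_term_cycle",4182.56,2927.79,5437.33,"gamma","published"
"cost.non_ic_bleed",1043.26,785.9,1192.06,"gamma","published"
"cost.crnm_bleed",133.56,113.86,147.78,"gamma","published"
"cost.pts_cycle",18,12.6,23.4,"gamma","published"
"util.baseline",0.825,0.81912,0.83088,"beta","published"
"util.ic_state",0.33,0.14,0.53,"beta","published"
"util.cteph_state",0.65,0.4,0.89,"beta","published"
"util.dec_apixaban",0.002,0,0.006,"beta","published"
"util.dec_lmwh_vka",0.013,0,0.026,"beta","published"
"util.dec_dvt",0.11,0,0.31,"beta","published"
"util.dec_pe",0.32,0.09,0.59,"beta","published"
"util.dec_non_ic_bleed",0.3,0.09,0.46,"beta","published"
"util.dec_crnm",0.0054,0,0.0195,"beta","published"
"util.dec_pts",0.07,0,0.24,"beta","published"
"policy.disc_after_non_ic",0.527,0.429142988314582,0.624857011685418,"beta","derived"
"policy.self_inject",0.92,0.64,1,"beta","published"
"mortality.hr_vte_history",2,NA,NA,"fixed","assumption"
"mortality.hr_cteph",4,NA,NA,"fixed","assumption"
"mortality.hr_post_ic",2.5,NA,NA,"fixed","assumption"
"longterm.late_recurrence.y0",0.11,NA,NA,"fixed","assumption"
"longterm.late_recurrence.y1",0.05,NA,NA,"fixed","assumption"
"longterm.late_recurrence.y5",0.03,NA,NA,"fixed","assumption"
"longterm.late_recurrence.y10",0.02,NA,NA,"fixed","assumption"
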