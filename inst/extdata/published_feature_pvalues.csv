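task_id,f01,f02,f03,f04,f05,f06,f07,f08,f09,f10,f11,f12,f13,f14,f15,f16,f17
T1,.233,.525,<.001,.152,.061,<.001,<.001,.033,.121,.261,.239,.014,.077,.237,.024,.274,<.001
T2,.730,.235,.013,.265,.451,<.001,.256,.017,.065,.057,.632,.155,.011,.489,.045,.006,<.001
T3,.625,.156,.071,.059,.077,.022,.366,.641,.095,.115,.541,.514,.513,.093,.336,.532,.019
T4,.254,.785,<.001,.082,.084,<.001,.514,.012,.025,.074,.365,.224,0.002,.258,.009,.008,<.001
T5,.299,,<.001,,,<.001,,,.054,,,.088,,,<.001,,.569
T6,<.001,,<.001,,,<.001,,,.006,,,.067,,,.399,,<.001
T7,.058,<.001,,<.001,,,,,,,,,,<.001,,,.029
T8,<.001,,,,.457,,<.001,,,,,,,,,.004,.006
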