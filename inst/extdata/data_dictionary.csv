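file,column,type,units,description
observation_log,worker_id,character,,Opaque identifier for one observed health extension worker
observation_log,setting,character,,Either urban or rural
observation_log,date,date (ISO-8601),,Calendar date of the observed activity event
observation_log,activity_label,character,,Raw activity label as recorded by the observer; resolved via the packaged synonym map
observation_log,duration_min,numeric,minutes,Duration of the contiguous activity event; must be non-negative
salary_survey,woreda_id,character,,Opaque identifier for the district (Woreda)
salary_survey,setting,character,,Either urban or rural
salary_survey,salary_low,numeric,birr/month,Lower bound of the reported salary range (equals salary_high for a point value)
salary_survey,salary_high,numeric,birr/month,Upper bound of the reported salary range
fee_schedule,category_id,character,,Stable identifier of the billable activity category
fee_schedule,display_name,character,,Human-readable activity name
fee_schedule,n_encounters,integer,count,Encounters kept after outlier exclusion (absent when built from printed inputs)
fee_schedule,pct_encounters,numeric,percent,Share of kept billable encounters in the setting
fee_schedule,mean_min,numeric,minutes,Mean encounter duration after outlier exclusion
fee_schedule,sd_min,numeric,minutes,Sample standard deviation of kept encounter durations
fee_schedule,base_birr,numeric,birr,Base salary cost per encounter (uplifted salary per minute times mean duration); half-up to 1 decimal
fee_schedule,base_usd,numeric,US$,Base salary cost per encounter in US dollars; half-up to 2 decimals
fee_schedule,cost82_birr,numeric,birr,Total cost per encounter at the 82% non-salary rate (management + overhead); base times 1.82
fee_schedule,cost82_usd,numeric,US$,82% scenario in US dollars
fee_schedule,cost270_birr,numeric,birr,Total cost per encounter at the 270% non-salary rate (supplies + management + overhead); base times 3.70
fee_schedule,cost270_usd,numeric,US$,270% scenario in US dollars
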