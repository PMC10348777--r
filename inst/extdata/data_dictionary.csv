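table,column,type,description
ed;inpatient,rln,string,Record linkage number; pseudonymous patient identifier; empty when missing
ed;inpatient,facility_id,string,Opaque facility identifier resolvable in hospitals.csv
ed;inpatient,record_kind,string,ED or INPATIENT
ed;inpatient,admit_date,date,Encounter admission date (ISO-8601; date only; no times)
ed;inpatient,discharge_date,date,Encounter discharge date (ISO-8601)
ed;inpatient,disposition,string,Raw discharge disposition code
ed;inpatient,admission_type,string,EMERGENT / ELECTIVE / OTHER
ed;inpatient,age,integer,Age in years at encounter
ed;inpatient,sex,string,MALE / FEMALE
ed;inpatient,race,string,Raw race code (see default_code_maps())
ed;inpatient,ethnicity,string,NON_HISPANIC / HISPANIC
ed;inpatient,insurance,string,Raw payer code (see default_code_maps())
ed;inpatient,riss,integer,Injury severity score derived upstream from diagnosis codes
ed;inpatient,mechanism,string,Raw injury mechanism code
ed;inpatient,body_region,string,Body region flag(s); semicolon separated when several
ed;inpatient,burn_flag,logical,Burn injury present
ed;inpatient,injury_dx,logical,Injury diagnosis present
ed;inpatient,year,integer,Calendar year of admit_date
ed;inpatient,surgery_class,string,Receiving-center surgery class (NONE/DIAGNOSTIC/MINOR_THERAPEUTIC/MAJOR_THERAPEUTIC); empty on ED rows
hospitals,facility_id,string,Opaque facility identifier
hospitals,name,string,Facility name
hospitals,latitude,double,WGS84 latitude
hospitals,longitude,double,WGS84 longitude
hospitals,facility_type,string,SHORT_TERM_ACUTE / REHAB / PSYCH / LONG_TERM / OTHER
hospitals,lemsa_id,string,Local EMS agency; each facility belongs to exactly one
hospitals,rtcc_id,string,Regional trauma coordinating committee of the LEMSA
hospitals,year,integer,Designation year (one row per facility-year)
hospitals,level,string,Annual trauma designation (NONTRAUMA/LEVEL_I/LEVEL_II/LEVEL_III/LEVEL_IV)
ground_truth,patient_id,string,Simulated patient identifier
ground_truth,rln,string,True record linkage number before missingness injection
ground_truth,true_retriage,logical,Patient is a true cohort re-triage (survives the full cascade)
ground_truth,true_label,string,OPTIMAL / SUBOPTIMAL for true re-triages; empty otherwise
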