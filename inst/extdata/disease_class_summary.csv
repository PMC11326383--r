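disease_class,n_phecodes,n_latent_factors,explained_variance_pct
Circulatory System,155,4,50.1
Congenital Anomalies,54,1,38.3
Dermatological,94,4,45.3
Digestive,155,6,48.3
Endocrine/Metabolic,146,2,51.5
Genitourinary,156,10,52.1
Hematopoietic,54,3,64.4
Infectious Diseases,55,2,44.7
Injuries and Poisonings,125,2,21.6
Mental Disorders,70,4,64.5
Musculoskeletal,120,2,36.0
Neoplasms,132,3,39.9
Neurological,78,5,53.5
Pregnancy Complications,44,1,22.9
Respiratory,75,6,64.0
Sense Organs,113,1,23.0
Symptoms,36,2,46.0
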