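pt,soc
Malignant neoplasm progression,"Neoplasms benign, malignant and unspecified"
Anaemia,Blood and lymphatic system disorders
Anemia,Blood and lymphatic system disorders
Febrile neutropenia,Blood and lymphatic system disorders
Neutropenia,Blood and lymphatic system disorders
Pyrexia,General disorders and administration site conditions
Neutrophil count decreased,Investigations
Pneumonia,Infections and infestations
Thrombocytopenia,Blood and lymphatic system disorders
Acute kidney injury,Renal and urinary disorders
Decreased appetite,Metabolism and nutrition disorders
Myelosuppression,Blood and lymphatic system disorders
Interstitial lung disease,"Respiratory, thoracic and mediastinal disorders"
Platelet count decreased,Investigations
Pancytopenia,Blood and lymphatic system disorders
Hypothyroidism,Endocrine disorders
Pneumonitis,"Respiratory, thoracic and mediastinal disorders"
Neuropathy peripheral,Nervous system disorders
Disease progression,General disorders and administration site conditions
White blood cell count decreased,Investigations
Colitis,Gastrointestinal disorders
Renal impairment,Renal and urinary disorders
General physical health deterioration,General disorders and administration site conditions
Sepsis,Infections and infestations
Adrenal insufficiency,Endocrine disorders
Immune-mediated enterocolitis,Gastrointestinal disorders
Hepatic function abnormal,Hepatobiliary disorders
Immune-mediated hepatic disorder,Hepatobiliary disorders
Hypokalaemia,Metabolism and nutrition disorders
Hyperthyroidism,Endocrine disorders
Leukopenia,Blood and lymphatic system disorders
Alanine aminotransferase increased,Investigations
Pulmonary embolism,Vascular disorders
Pleural effusion,"Respiratory, thoracic and mediastinal disorders"
Hyponatraemia,Metabolism and nutrition disorders
Hepatitis,Hepatobiliary disorders
Mucosal inflammation,Gastrointestinal disorders
Septic shock,Infections and infestations
Tubulointerstitial nephritis,Renal and urinary disorders
Stomatitis,Gastrointestinal disorders
Neoplasm progression,"Neoplasms benign, malignant and unspecified"
Aspartate aminotransferase increased,Investigations
Respiratory failure,"Respiratory, thoracic and mediastinal disorders"
Hepatic cytolysis,Hepatobiliary disorders
Myocarditis,Cardiac disorders
Cytokine release syndrome,Immune system disorders
Blood creatinine increased,Investigations
Rash maculo-papular,Skin and subcutaneous tissue disorders
Immune-mediated lung disease,"Respiratory, thoracic and mediastinal disorders"
Liver disorder,Hepatobiliary disorders
C-reactive protein increased,Investigations
Vomiting,Gastrointestinal disorders
Dyspnoea,"Respiratory, thoracic and mediastinal disorders"
Nausea,Gastrointestinal disorders
Diarrhoea,Gastrointestinal disorders
Fatigue,General disorders and administration site conditions
Delirium,Psychiatric disorders
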