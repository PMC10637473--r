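pt_code,pt_name,soc_code,soc_name
conjunctivitis,Conjunctivitis,EYE,Eye disorders
blepharitis,Blepharitis,EYE,Eye disorders
dry_eye,Dry eye,EYE,Eye disorders
corneal_erosion,Corneal erosion,EYE,Eye disorders
episcleritis,Episcleritis,EYE,Eye disorders
atopic_keratoconjunctivitis,Atopic keratoconjunctivitis,EYE,Eye disorders
cataract,Cataract,EYE,Eye disorders
keratoconus,Keratoconus,EYE,Eye disorders
eye_pruritus,Eye pruritus,EYE,Eye disorders
acne,Acne,SKIN,Skin and subcutaneous tissue disorders
dry_skin,Dry skin,SKIN,Skin and subcutaneous tissue disorders
alopecia,Alopecia,SKIN,Skin and subcutaneous tissue disorders
alopecia_totalis,Alopecia totalis,SKIN,Skin and subcutaneous tissue disorders
alopecia_areata,Alopecia areata,SKIN,Skin and subcutaneous tissue disorders
acanthosis_nigricans,Acanthosis nigricans,SKIN,Skin and subcutaneous tissue disorders
vitiligo,Vitiligo,SKIN,Skin and subcutaneous tissue disorders
erythema_nodosum,Erythema nodosum,SKIN,Skin and subcutaneous tissue disorders
pruritus,Pruritus,SKIN,Skin and subcutaneous tissue disorders
urticaria,Urticaria,SKIN,Skin and subcutaneous tissue disorders
psoriasis,Psoriasis,SKIN,Skin and subcutaneous tissue disorders
eye_infection,Eye infection,INF,Infections and infestations
staphylococcal_infection,Staphylococcal infection,INF,Infections and infestations
streptococcal_pharyngitis,Streptococcal pharyngitis,INF,Infections and infestations
nasopharyngitis,Nasopharyngitis,INF,Infections and infestations
oral_herpes,Oral herpes,INF,Infections and infestations
erysipelas,Erysipelas,INF,Infections and infestations
acarodermatitis,Acarodermatitis,INF,Infections and infestations
arthralgia,Arthralgia,MUSC,Musculoskeletal and connective tissue disorders
back_disorder,Back disorder,MUSC,Musculoskeletal and connective tissue disorders
seronegative_arthritis,Seronegative arthritis,MUSC,Musculoskeletal and connective tissue disorders
myalgia,Myalgia,MUSC,Musculoskeletal and connective tissue disorders
hypersensitivity,Hypersensitivity,IMM,Immune system disorders
anaphylactic_reaction,Anaphylactic reaction,IMM,Immune system disorders
hypereosinophilic_syndrome,Hypereosinophilic syndrome,BLOOD,Blood and lymphatic system disorders
cutaneous_t_cell_lymphoma,Cutaneous T-cell lymphoma,NEOP,Neoplasms benign malignant and unspecified
seminoma,Seminoma,NEOP,Neoplasms benign malignant and unspecified
knee_operation,Knee operation,SURG,Surgical and medical procedures
peak_expiratory_flow_rate_decreased,Peak expiratory flow rate decreased,INV,Investigations
pulmonary_congestion,Pulmonary congestion,RESP,"Respiratory, thoracic and mediastinal disorders"
hyposmia,Hyposmia,NERV,Nervous system disorders
headache,Headache,NERV,Nervous system disorders
injection_site_reaction,Injection site reaction,GEN,General disorders and administration site conditions
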