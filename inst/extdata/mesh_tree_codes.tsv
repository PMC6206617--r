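mesh_term	tree_codes
HYPERTENSION	C14
CARDIOVASCULAR DISEASES	C14
VASCULAR DISEASES	C14
HYPERTENSION, RENAL	C12;C14
HEART RATE	G09
BLOOD PRESSURE	G09
EPILEPSY	C10
SEIZURES	C10;C23
ANXIETY	F01
REFLEX, STARTLE	G11
MEMORY DISORDERS	C10;C23;F01
PAIN	C23
INFLAMMATION	C23
DEPRESSIVE DISORDER	F03
MENTAL DISORDERS	F03
AUTOIMMUNE DISEASES	C20
IMMUNE SYSTEM DISEASES	C20
COLITIS, ULCERATIVE	C06
INFLAMMATORY BOWEL DISEASES	C06
CROHN DISEASE	C06
DIGESTIVE SYSTEM DISEASES	C06
LIVER DISEASES	C06
LIVER CIRRHOSIS	C06
DIABETES MELLITUS	C18;C19
DIABETES MELLITUS, TYPE 1	C18;C19;C20
DIABETES MELLITUS, TYPE 2	C18;C19
GONADAL HORMONES	D06
CARCINOMA, LEWIS LUNG	C04
CARCINOMA	C04
NEOPLASMS, EXPERIMENTAL	C04
NEOPLASMS	C04
LEUKEMIA	C04
LEUKEMIA L1210	C04
ARTHRITIS, EXPERIMENTAL	C05
ARTHRITIS	C05
MALARIA	C03
RESPIRATORY TRACT DISEASES	C08
LIPID METABOLISM DISORDERS	C18
HYPERLIPIDEMIAS	C18
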