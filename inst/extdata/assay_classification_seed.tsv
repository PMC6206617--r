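assay_class_id	level1	level2	level3	source	patterns	pattern_flags	mesh_terms	inducer_compounds	control_compounds	provenance
AC_ADJARTH	Musculo-skeletal System	Anti-Inflammatory Activity	Adjuvant Arthritis in Rats	Hock_2016	[Aa]djuvant[ -]arthriti		ARTHRITIS, EXPERIMENTAL;ARTHRITIS	Freund's complete adjuvant		repo
AC_ANTIINFL	Musculo-skeletal System	Anti-Inflammatory Activity	General Anti-Inflammatory Models	phenotype	[Aa]nti-?[Ii]nflammatory		INFLAMMATION			repo
AC_PAW	Musculo-skeletal System	Anti-Inflammatory Activity	Paw Edema Test	Hock_2016	[Cc]arrageenan|[Pp]aw [Oo]?edema		INFLAMMATION	carrageenan;formaldehyde	indomethacin	repo
AC_RENHYP	Cardiovascular System	Cardiovascular analysis	Renal Hypertension	Hock_2016	[Rr]enal[ -]hypertensi		HYPERTENSION, RENAL;HYPERTENSION			repo
AC_ANG2	Cardiovascular System	Cardiovascular analysis	Angiotensin II Antagonism in Vivo	Hock_2016	[Aa]ngiotensin[ -]?II		HYPERTENSION;CARDIOVASCULAR DISEASES;VASCULAR DISEASES	angiotensin II		repo
AC_HR	Cardiovascular System	Cardiovascular analysis	Heart Rate Measurement	Hock_2016	[Hh]eart [Rr]ate|\bHR\b		HEART RATE			repo
AC_MBP	Cardiovascular System	Cardiovascular Safety Pharmacology	Cardiovascular Safety Pharmacology: Mean Blood Pressure or Mean Arteral Blood Pressure	Vogel_2013	[Mm]ean ([Aa]rter[ia]al )?[Bb]lood [Pp]ressure		BLOOD PRESSURE			repo
AC_RADHEAT	Nervous System	Central Analgesic Activity	Radiant Heat Method	Hock_2016	[Tt]ail\W?[Ff]lick|[Rr]adiant [Hh]eat		PAIN		morphine;codeine;meperidine	printed
AC_ANALG	Nervous System	General Analgesic Activity	General Analgesic Nociceptic and Allodynic Activity	phenotype	[Aa]nalgesi|[Aa]ntinocicepti|[Aa]llodyni		PAIN			repo
AC_WRITHE	Nervous System	Peripheral Analgesic Activity	Writhing Test for Analgesic Activity	Hock_2016	[Ww]rithing		PAIN	acetic acid;phenylquinone	aspirin	repo
AC_EPIL	Nervous System	Anti-Epileptic Activity	General Anti-Epileptic Activity	phenotype	[Aa]nti-?epileptic|[Aa]nticonvulsant|[Ss]eizure		EPILEPSY;SEIZURES	pentylenetetrazole		repo
AC_STARTLE	Nervous System	Tests for Anxiolytic Activity	Acoustic Startle Response in Rats	Hock_2016	[Aa]coustic [Ss]tartle		ANXIETY;REFLEX, STARTLE		diazepam	repo
AC_RAM	Nervous System	Learning and Memory	Spatial Discrimination Learning in the Radial Arm Maze	Vogel_2008	[Rr]adial[ -][Aa]rm [Mm]aze		MEMORY DISORDERS	scopolamine		repo
AC_SCOPAMN	Nervous System	Learning and Memory	Scopolamine Induced Amnesia in Mice Inhibitory-Avoidance Learning	Hock_2016	[Ss]copolamine[ -]induced		MEMORY DISORDERS	scopolamine		repo
AC_PASSAVOID	Nervous System	Learning and Memory	General Inhibitory (Passive) Avoidance Learning	phenotype	[Pp]assive[ -][Aa]voidance|[Ii]nhibitory[ -][Aa]voidance		MEMORY DISORDERS			repo
AC_LEARNMEM	Nervous System	Learning and Memory	General Learning and Memory Models	phenotype	[Aa]nti-?amnesic|[Aa]mnesi|[Mm]emory		MEMORY DISORDERS			repo
AC_SWIM	Nervous System	Tests for Anti-Depressant Activity	Despair Swim Test	Hock_2016	[Ff]orced swim|[Dd]espair [Ss]wim|[Bb]ehavioural despair		DEPRESSIVE DISORDER		imipramine	repo
AC_ANTIDEP	Nervous System	Tests for Anti-Depressant Activity	General Anti-Depressant Activity	phenotype	[Aa]nti-?depressant		DEPRESSIVE DISORDER;MENTAL DISORDERS			repo
AC_AUTOIMM	Antineoplastic and Immunomodulating Agents	Methods for Testing Immunological Factors	Spontaneous Autoimmune Diseases In Animals	Vogel_2008	[Aa]utoimmune		AUTOIMMUNE DISEASES;IMMUNE SYSTEM DISEASES			repo
AC_LEWIS	Antineoplastic and Immunomodulating Agents	Carcinoma Oncology Models	Lewis Lung Carcinoma	phenotype	[Ll]ewis [Ll]ung		CARCINOMA, LEWIS LUNG;CARCINOMA;NEOPLASMS, EXPERIMENTAL			repo
AC_LEUK	Antineoplastic and Immunomodulating Agents	Cytostatic Activity	General Leukemia	phenotype	[Ll]euka?emia		LEUKEMIA			repo
AC_L1210	Antineoplastic and Immunomodulating Agents	Leukemia Oncology Models	L1210 Experimental Leukemia	Hock_2016	L1210		LEUKEMIA L1210;LEUKEMIA			repo
AC_NEOPL	Antineoplastic and Immunomodulating Agents	General Antineoplastic Activity	Neoplasms	phenotype	[Aa]nti-?tumou?r|[Nn]eoplas		NEOPLASMS			repo
AC_COLITIS	Alimentary Tract and Metabolism	Intestinal Function	Experimental Colitis Inflammatory Gut Disease	Vogel_2008	[Cc]olitis		COLITIS, ULCERATIVE;INFLAMMATORY BOWEL DISEASES;CROHN DISEASE;DIGESTIVE SYSTEM DISEASES	dextran sulfate sodium;trinitrobenzenesulfonic acid		repo
AC_DILI	Alimentary Tract and Metabolism	Liver Function	General Models of Drug Induced Liver Injury	phenotype	[Hh]epatic injury|[Ll]iver injury|[Ll]iver fibrosis|[Dd]rug[ -]induced liver		LIVER DISEASES			repo
AC_HEPATOTOX	Alimentary Tract and Metabolism	Liver Function	General Models of Hepatotoxic and Hepatoprotective Activity	phenotype	[Hh]epatoprotect|[Hh]epatotoxic|[Ll]iver damage		LIVER DISEASES			repo
AC_CCL4	Alimentary Tract and Metabolism	Liver Function	Carbon tetrachloride CCl4 Induced Liver Fibrosis in Rats	Vogel_2008	CC[Ll]4|[Cc]arbon tetrachloride		LIVER CIRRHOSIS	carbon tetrachloride		repo
AC_LXR	Alimentary Tract and Metabolism	Measurement of Blood Glucose-Lowering and Antidiabetic Activity	Anti-Diabetic Effects of Liver X Receptor Agonists	Vogel_2008	[Ll]iver X [Rr]eceptor|\bLXR\b		DIABETES MELLITUS;DIABETES MELLITUS, TYPE 2;DIABETES MELLITUS, TYPE 1			repo
AC_HYPOLIP	Alimentary Tract and Metabolism	Lipid Metabolism	Hypolipidemic Activity in Rats	Vogel_2008	[Hh]ypolipid[ae]?emic		LIPID METABOLISM DISORDERS;HYPERLIPIDEMIAS			repo
AC_LIPID	Alimentary Tract and Metabolism	Lipid Metabolism	General Lipid Metabolism	phenotype	[Ll]ipid|[Tt]riglyceride|[Cc]holesterol		LIPID METABOLISM DISORDERS			repo
AC_ESTRO	Genito Urinary System and Sex Hormones	Ovarian Hormones	General Estrogen or Progestogen Activity	phenotype	[Ee]strogen|[Pp]rogest[oa]gen		GONADAL HORMONES		estradiol	repo
AC_AIRWAY	Respiratory System	Airway Models	General Airway Models	phenotype	[Aa]irway		RESPIRATORY TRACT DISEASES			repo
AC_MALARIA	Antiinfectives for Systemic Use	Antiparasitic Models	General Antimalarial Activity	phenotype	[Aa]nti-?malarial		MALARIA		chloroquine	repo
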