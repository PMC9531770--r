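concept_id	canonical_name	substance_class	synonyms
acetaminophen	acetaminophen	analgesics	paracetamol
acetylcysteine	acetylcysteine	respiratory tract agents	nac|n-acetylcysteine|acetylsteine
adrenergic_beta_antagonists	adrenergic beta-antagonists	beta blockers	beta blocker|beta blockers|beta-blocker|beta-blockers
antibiotics	antibiotics	antibiotics	antibiotic
antidepressive_agents	antidepressive agents	antidepressants	antidepressant|antidepressants
ascorbic_acid	ascorbic acid	vitamins	vitamin c
aspirin	aspirin	nonsteroidal anti-inflammatory agents	acetylsalicylic acid
benzodiazepines	benzodiazepines	benzodiazepines	benzodiazepine
bupropion_hydrochloride	bupropion hydrochloride	antidepressants	bupropion
cannabidiol	cannabidiol	cannabinoids	cbd
cetirizine_hydrochloride	cetirizine hydrochloride	histamine antagonists	cetirizine|ceterizine|ceterizine hydrochloride
chlorine	chlorine	chemicals
coenzyme_q10	coenzyme q10	nutritional supplements	coq10|ubiquinol
curcumin	curcumin	nutritional supplements	turmeric
diphenhydramine_hydrochloride	diphenhydramine hydrochloride	histamine antagonists	diphenhydramine
ergocalciferol	ergocalciferol	vitamins	vitamin d|vitamin d2|vitamin d3|cholecalciferol
famotidine	famotidine	histamine antagonists
fexofenadine	fexofenadine	histamine antagonists
fish_oils	fish oils	nutritional supplements	fish oil|omega 3|omega-3
fluoxetine	fluoxetine	antidepressants
fluvoxamine	fluvoxamine	antidepressants
gabapentin	gabapentin	anticonvulsants
histamine_antagonists	histamine antagonists	histamine antagonists	antihistamine|antihistamines|anti-histamine|anti-histamines
hydroxyzine	hydroxyzine	histamine antagonists
ibuprofen	ibuprofen	nonsteroidal anti-inflammatory agents
iron	iron	minerals
ivermectin	ivermectin	antiparasitic agents
l_theanine	l-theanine	nutritional supplements	theanine
loratadine	loratadine	histamine antagonists
lorazepam	lorazepam	benzodiazepines
magnesium	magnesium	minerals	magnesium glycinate|magnesium citrate
melatonin	melatonin	nutritional supplements
montelukast	montelukast	leukotriene antagonists
multivitamin_preparation	multivitamin preparation	vitamins	multivitamin|multivitamins|multi-vitamin
naltrexone	naltrexone	opioid antagonists	low dose naltrexone|ldn
naproxen	naproxen	nonsteroidal anti-inflammatory agents
nattokinase	nattokinase	nutritional supplements
niacin	niacin	vitamins	vitamin b3|nicotinic acid
nsaids	nonsteroidal anti-inflammatory agents	nonsteroidal anti-inflammatory agents	nsaid|nsaids
omeprazole	omeprazole	proton pump inhibitors
potassium	potassium	minerals
prednisone	prednisone	steroids	prednisolone
probiotics	probiotics	nutritional supplements	probiotic
propranolol	propranolol	beta blockers
quercetin	quercetin	nutritional supplements
ranitidine	ranitidine	histamine antagonists
selenium	selenium	minerals
sertraline	sertraline	antidepressants
steroids	steroids	steroids	steroid|corticosteroid|corticosteroids
thiamine	thiamine	vitamins	vitamin b1
vitamin_b12	vitamin b12	vitamins	cobalamin|methylcobalamin
vitamin_e	vitamin e	vitamins	tocopherol
vitamins	vitamins	vitamins	vitamin
zinc	zinc	minerals	zinc picolinate
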