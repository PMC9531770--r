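brand_name	concept_id
advil	ibuprofen
aleve	naproxen
allegra	fexofenadine
ativan	lorazepam
benadryl	diphenhydramine_hydrochloride
claritin	loratadine
deltasone	prednisone
inderal	propranolol
luvox	fluvoxamine
motrin	ibuprofen
neurontin	gabapentin
pepcid	famotidine
prilosec	omeprazole
prozac	fluoxetine
singulair	montelukast
tylenol	acetaminophen
wellbutrin	bupropion_hydrochloride
zantac	ranitidine
zoloft	sertraline
zyrtec	cetirizine_hydrochloride
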