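# Synthetic stand-in for an Anatomical Therapeutic Chemical (ATC) ingredient
# term list, used by the 1/0.5/0 medication-score feature. One term per line;
# matching is case-insensitive. Replace with a licensed ATC export for real use.
acetylsalicylic acid
morphine
morphine sulfate
glyceryl trinitrate
frusemide
furosemide
warfarin
warfarin sodium
insulin
insulin aspart
salbutamol
salbutamol sulfate
paracetamol
metoprolol
metoprolol tartrate
amoxicillin
amoxicillin and clavulanic acid
enoxaparin
enoxaparin sodium
digoxin
atorvastatin
ramipril
perindopril
perindopril arginine
gliclazide
levodopa
levodopa and decarboxylase inhibitor
phenytoin
phenytoin sodium
ipratropium bromide
tiotropium bromide
prednisolone
ceftriaxone
gentamicin
vancomycin
pantoprazole
ondansetron
oxycodone
oxycodone hydrochloride
tramadol
heparin
clopidogrel
amiodarone
spironolactone
hydrochlorothiazide
potassium chloride
sodium chloride
calcium carbonate
ferrous sulfate
folic acid
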