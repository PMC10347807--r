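substance,formulation,bnf_chapter,bnf_paragraph
atorvastatin,tablet,2,2.12
simvastatin,tablet,2,2.12
rosuvastatin,tablet,2,2.12
pravastatin,tablet,2,2.12
omeprazole,capsule,1,1.3.5
lansoprazole,capsule,1,1.3.5
ranitidine,tablet,1,1.3.1
aspirin,tablet,2,2.9
clopidogrel,tablet,2,2.9
warfarin,tablet,2,2.8.2
apixaban,tablet,2,2.8.2
rivaroxaban,tablet,2,2.8.2
edoxaban,tablet,2,2.8.2
colecalciferol,tablet,9,9.6.4
folic acid,tablet,9,9.1.2
ferrous fumarate,tablet,9,9.1.1
ferrous sulfate,tablet,9,9.1.1
alendronic acid,tablet,6,6.6.2
ramipril,tablet,2,2.5.5
lisinopril,tablet,2,2.5.5
perindopril,tablet,2,2.5.5
losartan,tablet,2,2.5.5
candesartan,tablet,2,2.5.5
amlodipine,tablet,2,2.6.2
felodipine,tablet,2,2.6.2
diltiazem,capsule,2,2.6.2
bisoprolol,tablet,2,2.4
atenolol,tablet,2,2.4
propranolol,tablet,2,2.4
bendroflumethiazide,tablet,2,2.2.1
indapamide,tablet,2,2.2.1
furosemide,tablet,2,2.2.2
bumetanide,tablet,2,2.2.2
spironolactone,tablet,2,2.2.3
doxazosin,tablet,2,2.5.4
metformin,tablet,6,6.1.2
gliclazide,tablet,6,6.1.2
sitagliptin,tablet,6,6.1.2
levothyroxine,tablet,6,6.2.1
prednisolone,tablet,6,6.3.2
paracetamol,tablet,4,4.7.1
codeine,tablet,4,4.7.2
co-codamol,tablet,4,4.7.1
tramadol,capsule,4,4.7.2
morphine,tablet,4,4.7.2
buprenorphine,patch,4,4.7.2
amitriptyline,tablet,4,4.3.1
citalopram,tablet,4,4.3.3
sertraline,tablet,4,4.3.3
mirtazapine,tablet,4,4.3.4
venlafaxine,tablet,4,4.3.4
gabapentin,capsule,4,4.8.1
pregabalin,capsule,4,4.8.1
levetiracetam,tablet,4,4.8.1
zopiclone,tablet,4,4.1.1
diazepam,tablet,4,4.1.2
risperidone,tablet,4,4.2.1
quetiapine,tablet,4,4.2.1
donepezil,tablet,4,4.11
naproxen,tablet,10,10.1.1
ibuprofen,tablet,10,10.1.1
allopurinol,tablet,10,10.1.4
salbutamol,inhaler,3,3.1.1
beclometasone,inhaler,3,3.2
salmeterol,inhaler,3,3.1.1
tiotropium,inhaler,3,3.1.2
montelukast,tablet,3,3.3.2
carbocisteine,capsule,3,3.7
tamsulosin,capsule,7,7.4.1
finasteride,tablet,6,6.4.2
solifenacin,tablet,7,7.4.2
oxybutynin,tablet,7,7.4.2
latanoprost,drops,11,11.6
timolol,drops,11,11.6
hypromellose,drops,11,11.8.1
betamethasone,cream,13,13.4
clotrimazole,cream,13,13.10.2
emollient,cream,13,13.2.1
insulin glargine,injection,6,6.1.1
mixed insulin,injection,6,6.1.1
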