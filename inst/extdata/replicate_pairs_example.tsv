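Rectal Mucosa Donor 29	Rectal Mucosa Donor 31
Foreskin Fibroblast Primary Cells skin01	Foreskin Fibroblast Primary Cells skin02
Foreskin Melanocyte Primary Cells skin01	Foreskin Melanocyte Primary Cells skin03
Foreskin Keratinocyte Primary Cells skin02	Foreskin Keratinocyte Primary Cells skin03
Skeletal Muscle Female	Skeletal Muscle Male
Primary hematopoietic stem cells G-CSF-mobilized Male	Primary hematopoietic stem cells G-CSF-mobilized Female
Fetal Brain Female	Fetal Brain Male
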