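disease_id	disease_name	tissue_groups
D004700	Endocrine System Diseases	adrenal_gland|pituitary_gland|thyroid_gland|parathyroid_gland
D014570	Urologic Diseases	urinary_bladder|kidney
D014565	Urogenital Diseases	urinary_bladder|kidney|reproductive_system
D009845	Oligospermia	reproductive_system
D006943	Hyperglycemia	hematological_system
D008107	Liver Diseases	liver
D007674	Kidney Diseases	kidney
D008171	Lung Diseases	lung
D001927	Brain Diseases	nervous_system
D006331	Heart Diseases	heart|vascular_system
D012871	Skin Diseases	skin
D013959	Thyroid Diseases	thyroid_gland
D005767	Gastrointestinal Diseases	gastrointestinal_tract
D007154	Immune System Diseases	immune_system
D009422	Nervous System Diseases	nervous_system
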