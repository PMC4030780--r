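format-version: 1.2
ontology: hpo-synthetic-subset
remark: Synthetic miniature phenotype ontology for packaged fixtures and simulations. Term ids are in a synthetic HP:9xxxxxx range; names mirror the higher-order categories used for fetal structural-abnormality phenotyping. Not the real Human Phenotype Ontology.

[Term]
id: HP:9000001
name: Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000010
name: Abnormality of skeletal morphology
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000020
name: Abnormality of the cardiovascular system
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000030
name: Abnormality of brain morphology
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000040
name: Abnormality of the kidney
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000050
name: Craniofacial abnormality
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000060
name: Abnormality of the limbs
is_a: HP:9000010 ! Abnormality of skeletal morphology

[Term]
id: HP:9000070
name: Abnormality of the gastrointestinal tract
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000080
name: Abnormality of the respiratory system
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000090
name: Abnormality of the genitourinary system
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000100
name: Neurodevelopmental abnormality
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000110
name: Abnormality of prenatal development or growth
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000120
name: Abnormality of the skin
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000130
name: Abnormality of the endocrine system
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000140
name: Abnormality of the liver
is_a: HP:9000070 ! Abnormality of the gastrointestinal tract

[Term]
id: HP:9000150
name: Abnormality of the immune system
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9000160
name: Abnormality of laterality
is_a: HP:9000001 ! Phenotypic abnormality (synthetic root)

[Term]
id: HP:9010001
name: Shortening of the long bones
is_a: HP:9000060 ! Abnormality of the limbs

[Term]
id: HP:9010002
name: Bowing of the femora
is_a: HP:9000060 ! Abnormality of the limbs

[Term]
id: HP:9010003
name: Narrow thorax
is_a: HP:9000010 ! Abnormality of skeletal morphology
is_a: HP:9000080 ! Abnormality of the respiratory system

[Term]
id: HP:9010004
name: Platyspondyly
is_a: HP:9000010 ! Abnormality of skeletal morphology

[Term]
id: HP:9010005
name: Talipes equinovarus
is_a: HP:9000060 ! Abnormality of the limbs

[Term]
id: HP:9010006
name: Polydactyly
is_a: HP:9000060 ! Abnormality of the limbs

[Term]
id: HP:9010007
name: Syndactyly
is_a: HP:9000060 ! Abnormality of the limbs

[Term]
id: HP:9010008
name: Abnormality of the ribs
is_a: HP:9000010 ! Abnormality of skeletal morphology

[Term]
id: HP:9010009
name: Abnormal curvature of the spine
is_a: HP:9000010 ! Abnormality of skeletal morphology

[Term]
id: HP:9010010
name: Limb reduction defect
is_a: HP:9000060 ! Abnormality of the limbs

[Term]
id: HP:9020001
name: Ventricular septal defect
is_a: HP:9000020 ! Abnormality of the cardiovascular system

[Term]
id: HP:9020002
name: Atrial septal defect
is_a: HP:9000020 ! Abnormality of the cardiovascular system

[Term]
id: HP:9020003
name: Atrioventricular septal defect
is_a: HP:9000020 ! Abnormality of the cardiovascular system

[Term]
id: HP:9020004
name: Tricuspid regurgitation
is_a: HP:9000020 ! Abnormality of the cardiovascular system

[Term]
id: HP:9020005
name: Truncus arteriosus
is_a: HP:9000020 ! Abnormality of the cardiovascular system

[Term]
id: HP:9020006
name: Interrupted aortic arch
is_a: HP:9000020 ! Abnormality of the cardiovascular system

[Term]
id: HP:9020007
name: Malposition of the great arteries
is_a: HP:9000020 ! Abnormality of the cardiovascular system
is_a: HP:9000160 ! Abnormality of laterality

[Term]
id: HP:9020008
name: Increased nuchal translucency
is_a: HP:9000110 ! Abnormality of prenatal development or growth

[Term]
id: HP:9020009
name: Pulmonic stenosis
is_a: HP:9000020 ! Abnormality of the cardiovascular system

[Term]
id: HP:9030001
name: Ventriculomegaly
is_a: HP:9000030 ! Abnormality of brain morphology

[Term]
id: HP:9030002
name: Agenesis of the corpus callosum
is_a: HP:9000030 ! Abnormality of brain morphology

[Term]
id: HP:9030003
name: Hydrocephalus
is_a: HP:9000030 ! Abnormality of brain morphology

[Term]
id: HP:9030004
name: Complex brain malformation
is_a: HP:9000030 ! Abnormality of brain morphology

[Term]
id: HP:9030005
name: Brain injury
is_a: HP:9000030 ! Abnormality of brain morphology

[Term]
id: HP:9040001
name: Renal agenesis
is_a: HP:9000040 ! Abnormality of the kidney
is_a: HP:9000090 ! Abnormality of the genitourinary system

[Term]
id: HP:9040002
name: Multicystic dysplastic kidney
is_a: HP:9000040 ! Abnormality of the kidney
is_a: HP:9000090 ! Abnormality of the genitourinary system

[Term]
id: HP:9050001
name: Facial cleft
is_a: HP:9000050 ! Craniofacial abnormality

[Term]
id: HP:9050002
name: Micrognathia
is_a: HP:9000050 ! Craniofacial abnormality

[Term]
id: HP:9050003
name: Orofacial anomalies
is_a: HP:9000050 ! Craniofacial abnormality

[Term]
id: HP:9050004
name: Cryptophthalmos
is_a: HP:9000050 ! Craniofacial abnormality

[Term]
id: HP:9070001
name: Esophageal atresia
is_a: HP:9000070 ! Abnormality of the gastrointestinal tract

[Term]
id: HP:9070002
name: Tracheoesophageal fistula
is_a: HP:9000070 ! Abnormality of the gastrointestinal tract
is_a: HP:9000080 ! Abnormality of the respiratory system

[Term]
id: HP:9070003
name: Pyloric stenosis
is_a: HP:9000070 ! Abnormality of the gastrointestinal tract

[Term]
id: HP:9090001
name: Anogenital abnormality
is_a: HP:9000090 ! Abnormality of the genitourinary system

[Term]
id: HP:9100001
name: Seizures
is_a: HP:9000100 ! Neurodevelopmental abnormality

[Term]
id: HP:9100002
name: Intellectual disability
is_a: HP:9000100 ! Neurodevelopmental abnormality

[Term]
id: HP:9100003
name: Fetal akinesia sequence
is_a: HP:9000100 ! Neurodevelopmental abnormality

[Term]
id: HP:9110001
name: Intrauterine growth restriction
is_a: HP:9000110 ! Abnormality of prenatal development or growth

[Term]
id: HP:9120001
name: Cafe-au-lait macules
is_a: HP:9000120 ! Abnormality of the skin

[Term]
id: HP:9130001
name: Panhypopituitarism
is_a: HP:9000130 ! Abnormality of the endocrine system

[Term]
id: HP:9140001
name: Hepatic dysfunction
is_a: HP:9000140 ! Abnormality of the liver

[Term]
id: HP:9150001
name: Severe combined immunodeficiency
is_a: HP:9000150 ! Abnormality of the immune system

[Term]
id: HP:9160001
name: Situs inversus
is_a: HP:9000160 ! Abnormality of laterality
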