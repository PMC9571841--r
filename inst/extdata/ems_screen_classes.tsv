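phenotypic_class	category	dominant	recessive	complex
I	Seedling lethality and albinism	0	243	10
II	Root development	5	177	13
III	Plant size, architecture, and branching	74	1038	84
IV	Leaf morphology and color	45	21	9
V	Shoot apical and leaf senescence	15	17	3
VI	Flowering time	0	2	2
VII	Inflorescence architecture	11	139	33
VIII	Flower morphology and color	17	182	21
IX	Flower abscission zone	2	3	0
X	Fruit setting	20	35	12
XI	Fruit morphology/color	14	197	18
XII	Parthenocarpy (seedless fruits)	0	218	21
XIII	Fruit ripening	11	55	12
XIV	Cuticle/cracked fruit	8	10	3
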