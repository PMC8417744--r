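name	formula	id
Glycine	C2H5NO2	HMDB0000123
Alanine	C3H7NO2	HMDB0000161
Serine	C3H7NO3	HMDB0000187
Proline	C5H9NO2	HMDB0000162
Valine	C5H11NO2	HMDB0000883
Threonine	C4H9NO3	HMDB0000167
Leucine	C6H13NO2	HMDB0000687
Asparagine	C4H8N2O3	HMDB0000168
Aspartate	C4H7NO4	HMDB0000191
Glutamine	C5H10N2O3	HMDB0000641
Glutamate	C5H9NO4	HMDB0000148
Lysine	C6H14N2O2	HMDB0000182
Methionine	C5H11NO2S	HMDB0000696
Histidine	C6H9N3O2	HMDB0000177
Phenylalanine	C9H11NO2	HMDB0000159
Arginine	C6H14N4O2	HMDB0000517
Tyrosine	C9H11NO3	HMDB0000158
Tryptophan	C11H12N2O2	HMDB0000929
Pyruvate	C3H4O3	HMDB0000243
Lactate	C3H6O3	HMDB0000190
Succinate	C4H6O4	HMDB0000254
Fumarate	C4H4O4	HMDB0000134
Malate	C4H6O5	HMDB0000156
Citrate	C6H8O7	HMDB0000094
Isocitrate	C6H8O7	HMDB0000193
Alpha-ketoglutarate	C5H6O5	HMDB0000208
2-Hydroxyglutarate	C5H8O5	HMDB0000606
Glucose	C6H12O6	HMDB0000122
Glucose 6-phosphate	C6H13O9P	HMDB0001401
Fructose 1,6-bisphosphate	C6H14O12P2	HMDB0001058
Glyceraldehyde 3-phosphate	C3H7O6P	HMDB0001112
3-Phosphoglycerate	C3H7O7P	HMDB0000807
Phosphoenolpyruvate	C3H5O6P	HMDB0000263
Ribose 5-phosphate	C5H11O8P	HMDB0001548
Sedoheptulose 7-phosphate	C7H15O10P	HMDB0001068
Erythrose 4-phosphate	C4H9O7P	HMDB0001321
Glutathione	C10H17N3O6S	HMDB0000125
Taurine	C2H7NO3S	HMDB0000251
Creatine	C4H9N3O2	HMDB0000064
Carnitine	C7H15NO3	HMDB0000062
Choline	C5H13NO	HMDB0000097
Hypoxanthine	C5H4N4O	HMDB0000157
Inosine	C10H12N4O5	HMDB0000195
Adenosine	C10H13N5O4	HMDB0000050
AMP	C10H14N5O7P	HMDB0000045
ATP	C10H16N5O13P3	HMDB0000538
NAD	C21H27N7O14P2	HMDB0000902
Uridine	C9H12N2O6	HMDB0000296
UMP	C9H13N2O9P	HMDB0000288
Citrulline	C6H13N3O3	HMDB0000904
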