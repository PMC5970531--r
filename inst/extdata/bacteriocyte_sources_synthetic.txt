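# Synthetic reconstruction of the 49-compound host-only bacteriocyte
# environment: nutrients a phloem-feeding insect host is predicted to
# provide to its bacteriocyte symbionts.  KEGG compound ids; composition
# follows the documented tiers (ATP, cofactors and vitamins such as NAD+,
# heme and thiamine, six non-essential amino acids, sugars, central-carbon
# intermediates and amino-acid precursors).
# -- energy currency, cofactors, vitamins --
C00002  # ATP
C00003  # NAD+
C00006  # NADP+
C00010  # coenzyme A
C00016  # FAD
C00061  # FMN
C00032  # heme
C00378  # thiamine
C00018  # pyridoxal 5'-phosphate
C00101  # tetrahydrofolate
C00120  # biotin
C00864  # pantothenate
C00255  # riboflavin
# -- non-essential amino acids (six) --
C00025  # L-glutamate
C00049  # L-aspartate
C00065  # L-serine
C00097  # L-cysteine
C00148  # L-proline
C00082  # L-tyrosine
# -- sugars and derivatives --
C00031  # D-glucose
C00095  # D-fructose
C00089  # sucrose
C00121  # D-ribose
C00116  # glycerol
C00092  # D-glucose 6-phosphate
C00085  # D-fructose 6-phosphate
# -- central carbon intermediates --
C00117  # D-ribose 5-phosphate
C00279  # D-erythrose 4-phosphate
C00074  # phosphoenolpyruvate
C00022  # pyruvate
C00026  # 2-oxoglutarate
C00036  # oxaloacetate
C00042  # succinate
C00122  # fumarate
C00149  # (S)-malate
C00024  # acetyl-CoA
# -- amino-acid precursors --
C00155  # L-homocysteine
C00141  # 3-methyl-2-oxobutanoate
C00671  # (S)-3-methyl-2-oxopentanoate
C00233  # 4-methyl-2-oxopentanoate
# -- inorganics and small molecules --
C00001  # H2O
C00009  # orthophosphate
C00013  # diphosphate
C00014  # ammonia
C00011  # CO2
C00007  # O2
C00059  # sulfate
C00288  # hydrogencarbonate
C00080  # H+
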