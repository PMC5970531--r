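# Synthetic reconstruction of the essential-metabolite target panel used
# to proxy growth capacity: amino acids, nucleotides and cofactors.
# KEGG compound ids.
C00037  # glycine
C00041  # L-alanine
C00183  # L-valine
C00123  # L-leucine
C00407  # L-isoleucine
C00148  # L-proline
C00065  # L-serine
C00188  # L-threonine
C00097  # L-cysteine
C00073  # L-methionine
C00049  # L-aspartate
C00152  # L-asparagine
C00025  # L-glutamate
C00064  # L-glutamine
C00047  # L-lysine
C00062  # L-arginine
C00135  # L-histidine
C00079  # L-phenylalanine
C00082  # L-tyrosine
C00078  # L-tryptophan
C00020  # AMP
C00144  # GMP
C00105  # UMP
C00055  # CMP
C00364  # dTMP
C00068  # thiamine diphosphate
C00019  # S-adenosyl-L-methionine
C00234  # 10-formyltetrahydrofolate
C00143  # 5,10-methylenetetrahydrofolate
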