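# Gene signatures used by the module-scoring functions. Edit freely:
# every scoring operation takes the signature list as input.
#
# Notes on provenance of the shipped lists:
# - cytotoxicity: 10 symbols as printed in the source method description,
#   although that description announces 11 genes; "KLRDC1" is not a
#   standard HGNC symbol and is most likely KLRD1 (CD94). The printed
#   symbol is kept here so the discrepancy stays visible.
# - ISG: the original 58-gene interferon-stimulated-gene list is cited
#   but not printed; this is a documented placeholder of canonical ISGs
#   and should be replaced with the curated list for real analyses.
# - GO-pathway signatures (response to type I interferon GO:0034340,
#   defense response to virus GO:0051607, T-cell activation GO:0042110,
#   B-cell activation GO:0042113, RNA splicing GO:0008380, alternative
#   mRNA splicing via spliceosome GO:0000380, TCR signalling GO:0050852,
#   BCR signalling GO:0050853) are config-supplied: resolve the term
#   membership with an annotation database and add them here.
cytotoxicity:
  role: cytotoxicity
  genes: [PRF1, IFNG, NKG7, GZMB, GZMA, GZMH, KLRK1, KLRDC1, CTSW, CST7]
apoptosis:
  role: apoptosis
  genes: [TNFSF10, TRADD, FAS, FASLG, FADD, TNFSF14, BAD, BAX, CASP4,
          DAP3, DAXX, PDCD10, PDCD6]
exhaustion:
  role: exhaustion
  genes: [LAG3, PDCD1, CTLA4, HAVCR2, TOX]
ISG:
  role: ISG
  genes: [STAT1, STAT2, IRF9, IRF7, ISG15, IFI6, IFI35, IFI44, IFI44L,
          IFIT1, IFIT3, IFITM1, IFITM3, MX1, MX2, OAS1, OAS2, OAS3,
          OASL, BST2, RSAD2, USP18, LY6E, XAF1, EPSTI1, HERC5, SAMD9,
          SAMD9L, PLSCR1, ZBP1, AIM2]
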