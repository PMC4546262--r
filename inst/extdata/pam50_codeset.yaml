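# Default codeset for the 50-gene intrinsic-subtype panel.
#
# classifier_genes: the published PAM50 panel (Parker et al. 2009,
#   J Clin Oncol 27:1160), modern HGNC symbols (NDC80 = KNTC2,
#   NUF2 = CDCA1, ORC6 = ORC6L).
# housekeeper_genes: the eight endogenous controls used by the
#   commercial nCounter assay. The assay literature cites but does not
#   enumerate them in the main text, so this list is a documented,
#   configurable default.
# positive_controls: six spike-in probes forming a linear titration;
#   concentrations in fM, the standard nCounter ERCC titration.
# negative_controls: eight probes with no transcriptome homology.
# proliferation_subset: the 11 co-regulated cell-cycle genes used by the
#   ROR-P score of Nielsen et al. 2010 (Clin Cancer Res 16:5222);
#   configurable.
# reduced_model_exclusions: the four genes dropped by the reduced
#   (46-gene) ROR variant.
schema: pamror-codeset/1
name: pam50_default
classifier_genes:
  - ACTR3B
  - ANLN
  - BAG1
  - BCL2
  - BIRC5
  - BLVRA
  - CCNB1
  - CCNE1
  - CDC20
  - CDC6
  - CDH3
  - CENPF
  - CEP55
  - CXXC5
  - EGFR
  - ERBB2
  - ESR1
  - EXO1
  - FGFR4
  - FOXA1
  - FOXC1
  - GPR160
  - GRB7
  - KIF2C
  - KRT14
  - KRT17
  - KRT5
  - MAPT
  - MDM2
  - MELK
  - MIA
  - MKI67
  - MLPH
  - MMP11
  - MYBL2
  - MYC
  - NAT1
  - NDC80
  - NUF2
  - ORC6
  - PGR
  - PHGDH
  - PTTG1
  - RRM2
  - SFRP1
  - SLC39A6
  - TMEM45B
  - TYMS
  - UBE2C
  - UBE2T
housekeeper_genes:
  - ACTB
  - GUSB
  - MRPL19
  - PSMC4
  - PUM1
  - RPLP0
  - SF3A1
  - TFRC
positive_controls:
  - id: POS_A
    concentration: 128.0
  - id: POS_B
    concentration: 32.0
  - id: POS_C
    concentration: 8.0
  - id: POS_D
    concentration: 2.0
  - id: POS_E
    concentration: 0.5
  - id: POS_F
    concentration: 0.125
negative_controls:
  - NEG_A
  - NEG_B
  - NEG_C
  - NEG_D
  - NEG_E
  - NEG_F
  - NEG_G
  - NEG_H
proliferation_subset:
  - BIRC5
  - CCNB1
  - CDC20
  - CEP55
  - MKI67
  - NDC80
  - NUF2
  - PTTG1
  - RRM2
  - TYMS
  - UBE2C
reduced_model_exclusions:
  - BIRC5
  - CCNB1
  - GRB7
  - MYBL2
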