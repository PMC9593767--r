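# Example functional signatures matching the planted programs of the
# synthetic cohort generator. Plain lists are scored as mean normalized
# expression; the aging signature carries +1/-1 weights and is scored as a
# weighted average of per-gene z-scores.
apoptosis:
  - CASP3
  - CASP8
  - BAX
  - BAK1
  - TP53
  - FAS
  - TNFRSF1A
  - APAF1
  - CYCS
  - DIABLO
  - BID
  - PMAIP1
maturation:
  - MMP8
  - CEACAM8
  - LTF
  - CAMP
  - LCN2
  - ARG1
  - ORM1
azurophil:
  - MPO
  - ELANE
  - PRTN3
  - CTSG
  - DEFA3
  - DEFA4
  - AZU1
ifn_response:
  - IFI6
  - MX1
  - OAS1
  - IFIT3
  - IRF7
  - SIGLEC1
aging:
  genes:
    - CXCR4
    - ICAM1
    - ITGAX
    - SELL
    - LRRN3
    - PTGER2
  weights: [1, 1, 1, -1, -1, -1]
neutrophil_markers:
  - FCGR3B
  - CXCR2
  - IL1R2
  - CD177
  - S100A9
  - CSF3R
immature_subtype:
  - MMP9
  - HP
  - RGL4
  - FCN1
  - OLFM4
  - PADI4
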