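# Example derived-trait definitions for a small O-glycopeptide panel.
# Each trait is a weighted sum over glycoform relative abundances on one
# peptide, divided by a weighted sum (or by 1 for a plain weighted sum).
- name: TPL_Sfrac
  peptide: TPL
  numerator:
    TPL_H5N5F1S1: 1
    TPL_H5N5F1S2: 1
  denominator:
    TPL_H5N5F1S0: 1
    TPL_H5N5F1S1: 1
    TPL_H5N5F1S2: 1
- name: TPL_nS
  peptide: TPL
  numerator:
    TPL_H5N5F1S1: 1
    TPL_H5N5F1S2: 2
  denominator:
    TPL_H5N5F1S0: 1
    TPL_H5N5F1S1: 1
    TPL_H5N5F1S2: 1
- name: HYT_nGal
  peptide: HYT
  numerator:
    HYT_H3N5F0S0: 3
    HYT_H3N5F0S1: 3
    HYT_H4N5F0S1: 4
  denominator:
    HYT_H3N5F0S0: 1
    HYT_H3N5F0S1: 1
    HYT_H4N5F0S1: 1
- name: LSL_Sfrac
  peptide: LSL
  numerator:
    LSL_H5N4F0S1: 1
  denominator:
    LSL_H5N4F0S0: 1
    LSL_H5N4F0S1: 1
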