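zinc_fingers:
  CI:
    anchors:
    - C
    - C
    - C
    - C
    spacers:
    - 2.0
    - 13.0
    - 2.0
  CII:
    anchors:
    - C
    - C
    - C
    - C
    spacers:
    - 5.0
    - 9.0
    - 2.0
  CHC2:
    anchors:
    - C
    - C
    - H
    - C
    spacers:
    - 6.0
    - 9.0
    - 2.0
spacer_tolerance: no
max_inter_finger_gap: 30.0
pp_signatures:
  A:
  - CEACKK-CEGCKG
  - CEACKK-CEACKG
  B:
  - CLPCKS-CEGCKK
  - CEACKS-CEGCKG
max_mismatch: 1.0
gbox:
  GENERAL: R[FRG]GR[YVMCLFIW]P
  A_VARIANT: R[FRG]GRQ[PS]
  B_VARIANT: K[FRG]GR[PH]
  C_AAVENAE: RDRRGP
gbox_strict_z: yes
cte_window: 30.0
tbox_min_len: 12.0
ntss:
  TREMATODE_A1: CNLGxKDRRP
  CESTODE_A1: TNDVTAMKEKTP
  A2_A3: '[ST]PExAFxQYQxR[MS]EGQx'
ti: '[FWY][ASI][KREG]xxxx[FL]xx[LVI]xxx[DS][QK]xx[LV][LIF]'
af2:
  GENERAL: '[YVMCLFIW][YVMCLFIW]xE[YVMCLFIW][YVMCLFIW]'
  A: '[YVMCLFIW][YVMCLFIW]x[EQR][YVMCLFIW][YVMCLFIW]'
  B: '[YVMCLFIW][YVMCLFIW]x[EK][YVMCLFIW][RKDENQ]'
  C_CBRENNERI: xx[YVMCLFIW][YVMCLFIW][YVMCLFIW][YVMCLFIW]
class_markers:
  class_I:
    E5: E
    E50: E
    KR55:
    - K
    - R
    RK93:
    - R
    - K
  class_II:
    ED42:
    - E
    - D
    E50: E
    R62: R
    HRK90:
    - H
    - R
    - K
column_map:
  E5: 4.0
  ED42: 41.0
  E50: 49.0
  KR55: 54.0
  R62: 61.0
  HRK90: 89.0
  RK93: 92.0
alignment:
  substitution_matrix: BLOSUM62
  gap_open: 10.0
  gap_extend: 1.0
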