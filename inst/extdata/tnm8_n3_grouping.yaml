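# Pathological TNM stage grouping (UICC/AJCC 8th edition) for M0 gastric
# cancer restricted to the N3 cells. The same grouping is reused by the
# modified system, with the N3a/N3b boundary moved to the scan-selected
# MLN cutoff.
edition: "8th"
stage_order: [IIB, IIIA, IIIB, IIIC]
grouping:
  T1:  {N3a: IIB,  N3b: IIIB}
  T2:  {N3a: IIIA, N3b: IIIB}
  T3:  {N3a: IIIB, N3b: IIIC}
  T4a: {N3a: IIIB, N3b: IIIC}
  T4b: {N3a: IIIC, N3b: IIIC}
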