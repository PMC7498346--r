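# SYNTHETIC default docking-strand library.
#
# Exchange-PAINT practice uses a series of short orthogonal docking strands
# (P0, P1, ...) whose reverse complements are the dye-bearing imager strands.
# The published library sequences are not redistributed here; the 13 entries
# below are synthetic 9-nt stand-ins with low mutual complementarity, intended
# for testing and as a template. Replace this file (or pass `library_path`)
# with your laboratory's own docking sequences before ordering probes.
docking_strands:
  P0: CCAGTTGAT
  P1: GTGCATCCA
  P2: TTCACCATT
  P3: AACTTTACT
  P4: CCTCTAATG
  P5: ATAGATTAT
  P6: TAACCGATG
  P7: TTGTTTTGT
  P8: CCAGCTTCC
  P9: GGACAAGAG
  P10: TTTTAGTGG
  P11: CCAAGGCGA
  P12: AAGAAAATA
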