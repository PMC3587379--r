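ID TATA
NA TATA box (synthetic consensus-derived profile, TATAWAW)
P0      A      C      G      T
01      5      5      5     85
02     85      5      5      5
03      5      5      5     85
04     85      5      5      5
05     45      5      5     45
06     85      5      5      5
07     45      5      5     45
//
ID CCAAT
NA CCAAT box (synthetic consensus-derived profile)
P0      A      C      G      T
01      5     85      5      5
02      5     85      5      5
03     85      5      5      5
04     85      5      5      5
05      5      5      5     85
//
ID GC
NA GC box (synthetic consensus-derived profile, GGGCGG)
P0      A      C      G      T
01      5      5     85      5
02      5      5     85      5
03      5      5     85      5
04      5     85      5      5
05      5      5     85      5
06      5      5     85      5
//
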