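compound,strain,gram,mic_uM,mbc_uM
DPPC80_C12T20,A. baumannii,negative,>570,>570
DPPC80_C12T20,E. coli,negative,>570,>570
DPPC80_C12T20,K. aerogenes,negative,>570,>570
DPPC80_C12T20,S. epidermidis,positive,>570,>570
DPPC80_C12T20,E. faecalis,positive,>570,>570
DPPC80_C12T20,S. aureus,positive,>570,>570
DPPC80_C12T20,L. monocytogenes,positive,>570,>570
DPPC80_C12T20,B. subtilis,positive,>570,>570
DPPC60_C12T40,A. baumannii,negative,>570,>570
DPPC60_C12T40,E. coli,negative,570,>570
DPPC60_C12T40,K. aerogenes,negative,570,>570
DPPC60_C12T40,S. epidermidis,positive,570,>570
DPPC60_C12T40,E. faecalis,positive,570,>570
DPPC60_C12T40,S. aureus,positive,570,>570
DPPC60_C12T40,L. monocytogenes,positive,-,>570
DPPC60_C12T40,B. subtilis,positive,570,>570
DPPC40_C12T60,A. baumannii,negative,>570,>570
DPPC40_C12T60,E. coli,negative,380,>570
DPPC40_C12T60,K. aerogenes,negative,380,>570
DPPC40_C12T60,S. epidermidis,positive,380,>570
DPPC40_C12T60,E. faecalis,positive,380,>570
DPPC40_C12T60,S. aureus,positive,380,>570
DPPC40_C12T60,L. monocytogenes,positive,-,>570
DPPC40_C12T60,B. subtilis,positive,380,>570
DPPC20_C12T80,A. baumannii,negative,380,380
DPPC20_C12T80,E. coli,negative,47,47
DPPC20_C12T80,K. aerogenes,negative,47,47
DPPC20_C12T80,S. epidermidis,positive,23,23
DPPC20_C12T80,E. faecalis,positive,23,23
DPPC20_C12T80,S. aureus,positive,23,23
DPPC20_C12T80,L. monocytogenes,positive,190,380
DPPC20_C12T80,B. subtilis,positive,23,23
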