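compound,strain,gram,mic_uM,mbc_uM
C8TC3NH3Cl,A. baumannii,negative,500,>500
C8TC3NH3Cl,E. coli,negative,500,>500
C8TC3NH3Cl,K. aerogenes,negative,>500,>500
C8TC3NH3Cl,S. epidermidis,positive,250,500
C8TC3NH3Cl,E. faecalis,positive,500,>500
C8TC3NH3Cl,S. aureus,positive,250,500
C8TC3NH3Cl,L. monocytogenes,positive,500,>500
C8TC3NH3Cl,B. subtilis,positive,250,500
C10TC3NH3Cl,A. baumannii,negative,500,500
C10TC3NH3Cl,E. coli,negative,125,125
C10TC3NH3Cl,K. aerogenes,negative,500,500
C10TC3NH3Cl,S. epidermidis,positive,62,250
C10TC3NH3Cl,E. faecalis,positive,62,125
C10TC3NH3Cl,S. aureus,positive,62,62
C10TC3NH3Cl,L. monocytogenes,positive,250,250
C10TC3NH3Cl,B. subtilis,positive,125,125
C12TC3NH3Cl,A. baumannii,negative,250,250
C12TC3NH3Cl,E. coli,negative,31,62
C12TC3NH3Cl,K. aerogenes,negative,125,125
C12TC3NH3Cl,S. epidermidis,positive,16,31
C12TC3NH3Cl,E. faecalis,positive,16,62
C12TC3NH3Cl,S. aureus,positive,8,8
C12TC3NH3Cl,L. monocytogenes,positive,62,62
C12TC3NH3Cl,B. subtilis,positive,15,31
C14TC3NH3Cl,A. baumannii,negative,125,125
C14TC3NH3Cl,E. coli,negative,125,500
C14TC3NH3Cl,K. aerogenes,negative,250,250
C14TC3NH3Cl,S. epidermidis,positive,8,31
C14TC3NH3Cl,E. faecalis,positive,16,31
C14TC3NH3Cl,S. aureus,positive,4,16
C14TC3NH3Cl,L. monocytogenes,positive,31,31
C14TC3NH3Cl,B. subtilis,positive,8,31
BAC,A. baumannii,negative,62,-
BAC,E. coli,negative,62,-
BAC,K. aerogenes,negative,62,-
BAC,S. epidermidis,positive,16,-
BAC,E. faecalis,positive,8,-
BAC,S. aureus,positive,16,-
BAC,L. monocytogenes,positive,62,-
BAC,B. subtilis,positive,16,-
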