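compound,strain,gram,mic_uM,mbc_uM
C10PC3NH3Cl,A. baumannii,negative,>500,>500
C10PC3NH3Cl,E. coli,negative,250,250
C10PC3NH3Cl,K. aerogenes,negative,500,500
C10PC3NH3Cl,S. epidermidis,positive,125,125
C10PC3NH3Cl,E. faecalis,positive,250,500
C10PC3NH3Cl,S. aureus,positive,250,250
C10PC3NH3Cl,L. monocytogenes,positive,500,500
C10PC3NH3Cl,B. subtilis,positive,250,500
C12PC3NH3Cl,A. baumannii,negative,125,125
C12PC3NH3Cl,E. coli,negative,31,31
C12PC3NH3Cl,K. aerogenes,negative,31,31
C12PC3NH3Cl,S. epidermidis,positive,31,31
C12PC3NH3Cl,E. faecalis,positive,16,31
C12PC3NH3Cl,S. aureus,positive,31,125
C12PC3NH3Cl,L. monocytogenes,positive,31,31
C12PC3NH3Cl,B. subtilis,positive,31,31
C14PC3NH3Cl,A. baumannii,negative,62.5,125
C14PC3NH3Cl,E. coli,negative,500,500
C14PC3NH3Cl,K. aerogenes,negative,500,500
C14PC3NH3Cl,S. epidermidis,positive,31,125
C14PC3NH3Cl,E. faecalis,positive,31,62
C14PC3NH3Cl,S. aureus,positive,62,125
C14PC3NH3Cl,L. monocytogenes,positive,31,62
C14PC3NH3Cl,B. subtilis,positive,62,125
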