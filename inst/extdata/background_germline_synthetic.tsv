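# categories: 96 pyrimidine-centered trinucleotide contexts, type-major order
category	probability
A[C>A]A	0.003597374623747
A[C>A]C	0.00860044640107018
A[C>A]G	0.00604087442001643
A[C>A]T	0.010764579723416
C[C>A]A	0.00458501362739922
C[C>A]C	0.00797161920289059
C[C>A]G	0.00706804852902011
C[C>A]T	0.00768673762590383
G[C>A]A	0.00405419579749638
G[C>A]C	0.00607952759857129
G[C>A]G	0.00455839303753232
G[C>A]T	0.00542963942287106
T[C>A]A	0.00398100322853534
T[C>A]C	0.00484948639471013
T[C>A]G	0.00461014096100256
T[C>A]T	0.00513716111659863
A[C>G]A	0.00278109362206421
A[C>G]C	0.00583454650883637
A[C>G]G	0.00442806975412073
A[C>G]T	0.00752379450935815
C[C>G]A	0.00407624887099101
C[C>G]C	0.00613080240309203
C[C>G]G	0.00535555198137766
C[C>G]T	0.0070722114562909
G[C>G]A	0.00353759236135371
G[C>G]C	0.00626181522816133
G[C>G]G	0.00532226562416384
G[C>G]T	0.0066435247436504
T[C>G]A	0.00301775399165538
T[C>G]C	0.00411182555215918
T[C>G]G	0.00428391060563863
T[C>G]T	0.00586387949791829
A[C>T]A	0.0165456772531686
A[C>T]C	0.0259992877925686
A[C>T]G	0.0165456772531686
A[C>T]T	0.0407921053921019
C[C>T]A	0.0195539088598152
C[C>T]C	0.0280422699097494
C[C>T]G	0.0195539088598152
C[C>T]T	0.041176688656432
G[C>T]A	0.0144219767176906
G[C>T]C	0.02037786904237
G[C>T]G	0.0144219767176906
G[C>T]T	0.0284085950506972
T[C>T]A	0.0138820594582857
T[C>T]C	0.023024212849065
T[C>T]G	0.0138820594582857
T[C>T]T	0.0260341899961054
A[T>A]A	0.00228274412737125
A[T>A]C	0.00495809439898082
A[T>A]G	0.00397781095779908
A[T>A]T	0.00524510608208164
C[T>A]A	0.00373853238378882
C[T>A]C	0.00600021048238348
C[T>A]G	0.00476321997549602
C[T>A]T	0.00808946792659246
G[T>A]A	0.00187958014318314
G[T>A]C	0.00411130583696066
G[T>A]G	0.00310258830017853
G[T>A]T	0.00463642696326618
T[T>A]A	0.00255296050396354
T[T>A]C	0.00365432707646839
T[T>A]G	0.0028136717712374
T[T>A]T	0.00432705467476974
A[T>C]A	0.0115444797406229
A[T>C]C	0.0193783229470968
A[T>C]G	0.0207538168316926
A[T>C]T	0.0230279781630085
C[T>C]A	0.0123420607335042
C[T>C]C	0.0259980991497222
C[T>C]G	0.0208076310526295
C[T>C]T	0.0400088112136718
G[T>C]A	0.00952038970307724
G[T>C]C	0.0162815264416161
G[T>C]G	0.0180821044895097
G[T>C]T	0.0196185597282468
T[T>C]A	0.00820543734597619
T[T>C]C	0.0162377572888632
T[T>C]G	0.0110495319246068
T[T>C]T	0.0165601023941449
A[T>G]A	0.00481725304408205
A[T>G]C	0.00734589168955167
A[T>G]G	0.00515216724489137
A[T>G]T	0.00771921349271195
C[T>G]A	0.00460661729376757
C[T>G]C	0.00998193992778488
C[T>G]G	0.00710699931179048
C[T>G]T	0.0116467375057246
G[T>G]A	0.00402094197944692
G[T>G]C	0.0101887196518135
G[T>G]G	0.00545147481392832
G[T>G]T	0.00694759966816678
T[T>G]A	0.00292874445299138
T[T>G]C	0.00681995436374234
T[T>G]G	0.0036495100418231
T[T>G]T	0.00614493307664996
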