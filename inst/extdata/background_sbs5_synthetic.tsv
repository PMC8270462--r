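# categories: 96 pyrimidine-centered trinucleotide contexts, type-major order
category	probability
A[C>A]A	0.00352776393659349
A[C>A]C	0.0081810477292628
A[C>A]G	0.00617996692055224
A[C>A]T	0.0104998964428443
C[C>A]A	0.00441949603224714
C[C>A]C	0.00752768537144036
C[C>A]G	0.00677322494364861
C[C>A]T	0.00791477607706656
G[C>A]A	0.00380303384513506
G[C>A]C	0.00576933328446513
G[C>A]G	0.00488959371516407
G[C>A]T	0.00517267218319534
T[C>A]A	0.00384538602246549
T[C>A]C	0.00459216267811264
T[C>A]G	0.00487374299246665
T[C>A]T	0.0050883206510868
A[C>G]A	0.00266620141261554
A[C>G]C	0.00557366017691038
A[C>G]G	0.00412350238747602
A[C>G]T	0.00765410303573998
C[C>G]A	0.00500145989735494
C[C>G]C	0.00601738073020065
C[C>G]G	0.00567397373373194
C[C>G]T	0.00670601820539438
G[C>G]A	0.00367091344621321
G[C>G]C	0.00599564251107322
G[C>G]G	0.00562779970570641
G[C>G]T	0.00622371951905436
T[C>G]A	0.00308143400257214
T[C>G]C	0.00388534445794192
T[C>G]G	0.00436116683677158
T[C>G]T	0.00587752966730962
A[C>T]A	0.0186851436583895
A[C>T]C	0.0248941821527146
A[C>T]G	0.0186851436583895
A[C>T]T	0.0470108896668509
C[C>T]A	0.0194272519603962
C[C>T]C	0.0277869960379182
C[C>T]G	0.0194272519603962
C[C>T]T	0.0420062831126531
G[C>T]A	0.0139981826855935
G[C>T]C	0.0202527487441598
G[C>T]G	0.0139981826855935
G[C>T]T	0.0269779941842815
T[C>T]A	0.0129875168527816
T[C>T]C	0.0240347952961844
T[C>T]G	0.0129875168527816
T[C>T]T	0.0255846627241725
A[T>A]A	0.00217893922497535
A[T>A]C	0.00538183566059784
A[T>A]G	0.00388217422060184
A[T>A]T	0.00500651611636407
C[T>A]A	0.00387281995453749
C[T>A]C	0.00585514378706131
C[T>A]G	0.00450515211332426
C[T>A]T	0.00800821644734978
G[T>A]A	0.00181287081927543
G[T>A]C	0.00393959581989521
G[T>A]G	0.00296508247759222
G[T>A]T	0.00501843442367477
T[T>A]A	0.00245283689569069
T[T>A]C	0.00354110376647618
T[T>A]G	0.00268888520912364
T[T>A]T	0.00407761251642416
A[T>C]A	0.0118420057958496
A[T>C]C	0.0196351967524416
A[T>C]G	0.0211722489539902
A[T>C]T	0.0219794517731405
C[T>C]A	0.0121765660597186
C[T>C]C	0.0266227051203274
C[T>C]G	0.0196958181216677
C[T>C]T	0.0378265582141747
G[T>C]A	0.00996622859247275
G[T>C]C	0.0178654454433437
G[T>C]G	0.0184536768750937
G[T>C]T	0.0193594611975432
T[T>C]A	0.00769063247588734
T[T>C]C	0.0152577826760917
T[T>C]G	0.0104328695256067
T[T>C]T	0.0170949643703092
A[T>G]A	0.00512418223005106
A[T>G]C	0.00710394558604095
A[T>G]G	0.00504508302489881
A[T>G]T	0.00735467484781382
C[T>G]A	0.00445741865732938
C[T>G]C	0.0100861610288472
C[T>G]G	0.00679246955978274
C[T>G]T	0.01132337446105
G[T>G]A	0.00390532385125206
G[T>G]C	0.0098255569913054
G[T>G]G	0.00544928066023635
G[T>G]T	0.00787541414068733
T[T>G]A	0.0028018142505651
T[T>G]C	0.00706341452638254
T[T>G]G	0.00359603892822464
T[T>G]T	0.00599432106984031
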