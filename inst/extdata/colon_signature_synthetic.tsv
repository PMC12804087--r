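channel	count	opportunity	frequency
A[C>A]A	NA	NA	0.00396825396825397
A[C>A]C	NA	NA	0.00396825396825397
A[C>A]G	NA	NA	0.00396825396825397
A[C>A]T	NA	NA	0.00396825396825397
C[C>A]A	NA	NA	0.00396825396825397
C[C>A]C	NA	NA	0.00396825396825397
C[C>A]G	NA	NA	0.00396825396825397
C[C>A]T	NA	NA	0.00396825396825397
G[C>A]A	NA	NA	0.00396825396825397
G[C>A]C	NA	NA	0.00396825396825397
G[C>A]G	NA	NA	0.00396825396825397
G[C>A]T	NA	NA	0.00396825396825397
T[C>A]A	NA	NA	0.00396825396825397
T[C>A]C	NA	NA	0.00396825396825397
T[C>A]G	NA	NA	0.00396825396825397
T[C>A]T	NA	NA	0.00396825396825397
A[C>G]A	NA	NA	0.00396825396825397
A[C>G]C	NA	NA	0.00396825396825397
A[C>G]G	NA	NA	0.00396825396825397
A[C>G]T	NA	NA	0.00396825396825397
C[C>G]A	NA	NA	0.00396825396825397
C[C>G]C	NA	NA	0.00396825396825397
C[C>G]G	NA	NA	0.00396825396825397
C[C>G]T	NA	NA	0.00396825396825397
G[C>G]A	NA	NA	0.00396825396825397
G[C>G]C	NA	NA	0.00396825396825397
G[C>G]G	NA	NA	0.00396825396825397
G[C>G]T	NA	NA	0.00396825396825397
T[C>G]A	NA	NA	0.00396825396825397
T[C>G]C	NA	NA	0.00396825396825397
T[C>G]G	NA	NA	0.00396825396825397
T[C>G]T	NA	NA	0.00396825396825397
A[C>T]A	NA	NA	0.00396825396825397
A[C>T]C	NA	NA	0.00396825396825397
A[C>T]G	NA	NA	0.158730158730159
A[C>T]T	NA	NA	0.00396825396825397
C[C>T]A	NA	NA	0.00396825396825397
C[C>T]C	NA	NA	0.00396825396825397
C[C>T]G	NA	NA	0.158730158730159
C[C>T]T	NA	NA	0.00396825396825397
G[C>T]A	NA	NA	0.00396825396825397
G[C>T]C	NA	NA	0.00396825396825397
G[C>T]G	NA	NA	0.158730158730159
G[C>T]T	NA	NA	0.00396825396825397
T[C>T]A	NA	NA	0.00396825396825397
T[C>T]C	NA	NA	0.00396825396825397
T[C>T]G	NA	NA	0.158730158730159
T[C>T]T	NA	NA	0.00396825396825397
A[T>A]A	NA	NA	0.00396825396825397
A[T>A]C	NA	NA	0.00396825396825397
A[T>A]G	NA	NA	0.00396825396825397
A[T>A]T	NA	NA	0.00396825396825397
C[T>A]A	NA	NA	0.00396825396825397
C[T>A]C	NA	NA	0.00396825396825397
C[T>A]G	NA	NA	0.00396825396825397
C[T>A]T	NA	NA	0.00396825396825397
G[T>A]A	NA	NA	0.00396825396825397
G[T>A]C	NA	NA	0.00396825396825397
G[T>A]G	NA	NA	0.00396825396825397
G[T>A]T	NA	NA	0.00396825396825397
T[T>A]A	NA	NA	0.00396825396825397
T[T>A]C	NA	NA	0.00396825396825397
T[T>A]G	NA	NA	0.00396825396825397
T[T>A]T	NA	NA	0.00396825396825397
A[T>C]A	NA	NA	0.00396825396825397
A[T>C]C	NA	NA	0.00396825396825397
A[T>C]G	NA	NA	0.00396825396825397
A[T>C]T	NA	NA	0.00396825396825397
C[T>C]A	NA	NA	0.00396825396825397
C[T>C]C	NA	NA	0.00396825396825397
C[T>C]G	NA	NA	0.00396825396825397
C[T>C]T	NA	NA	0.00396825396825397
G[T>C]A	NA	NA	0.00396825396825397
G[T>C]C	NA	NA	0.00396825396825397
G[T>C]G	NA	NA	0.00396825396825397
G[T>C]T	NA	NA	0.00396825396825397
T[T>C]A	NA	NA	0.00396825396825397
T[T>C]C	NA	NA	0.00396825396825397
T[T>C]G	NA	NA	0.00396825396825397
T[T>C]T	NA	NA	0.00396825396825397
A[T>G]A	NA	NA	0.00396825396825397
A[T>G]C	NA	NA	0.00396825396825397
A[T>G]G	NA	NA	0.00396825396825397
A[T>G]T	NA	NA	0.00396825396825397
C[T>G]A	NA	NA	0.00396825396825397
C[T>G]C	NA	NA	0.00396825396825397
C[T>G]G	NA	NA	0.00396825396825397
C[T>G]T	NA	NA	0.00396825396825397
G[T>G]A	NA	NA	0.00396825396825397
G[T>G]C	NA	NA	0.00396825396825397
G[T>G]G	NA	NA	0.00396825396825397
G[T>G]T	NA	NA	0.00396825396825397
T[T>G]A	NA	NA	0.00396825396825397
T[T>G]C	NA	NA	0.00396825396825397
T[T>G]G	NA	NA	0.00396825396825397
T[T>G]T	NA	NA	0.00396825396825397
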