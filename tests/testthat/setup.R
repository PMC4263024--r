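## Dense-matrix work in these tests runs fastest with the BLAS kept on a
## single thread (the optimizer's matvecs are too small to parallelize well).
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
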