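PKG_CPPFLAGS = -I$(R_HOME)/../../include
PKG_LIBS = -L$(R_HOME)/../../lib -lfftw3 $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
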