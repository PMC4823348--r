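PKG_LIBS = $(shell "${R_HOME}/bin/Rscript" -e 'cat(Rhdf5lib::pkgconfig("PKG_C_HL_LIBS"))')
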