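# The filtering and quantization kernels are dense floating-point loops;
# build them for the machine the package is installed on.
PKG_CXXFLAGS = -O3 -march=native -funroll-loops
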