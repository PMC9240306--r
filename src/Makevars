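# Build with the system toolchain: the conda cross-compiler targets a
# newer glibc than the runtime loader provides, so its objects fail to
# load; the system g++ links against the system libm/libc.
override CXX = g++ -std=gnu++17
override CXX17 = g++
override SHLIB_CXXLD = g++ -std=gnu++17
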