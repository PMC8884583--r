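CXX_STD = CXX17
# the fixed-width inner loops of the network passes vectorize only at -O3;
# a target-specific append wins over the site Makeconf optimization level
network.o: ALL_CXXFLAGS += -O3
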