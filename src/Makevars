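# Keep double arithmetic op-for-op IEEE (no fused multiply-add), so the
# compiled engine agrees bit-exactly with the plain-R reference semantics.
PKG_CXXFLAGS = -ffp-contract=off
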