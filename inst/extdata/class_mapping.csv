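tag,code
water,11
beach,31
urban,21
urban,22
urban,23
urban,24
forest,41
forest,42
forest,43
wetland,90
wetland,95
agriculture,81
agriculture,82
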