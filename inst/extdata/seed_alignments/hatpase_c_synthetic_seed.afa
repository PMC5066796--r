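>HATPASE_C_CONS
ICTARKGCISMAWAIWTFREDLRPGEVIRLEVDPNKLTVEWANGIEQMILSQGYKAAIWDPGGLGLRWPK
>mut1
ICTARKGLIVMAWAIWTFREDLRPGEVIRLEVDPNKLTVEWANGREQMIESQGYKAAIWSPGGLGLRWPK
>mut2
ICTARKSCISMAWAIWTFREDLRPGGVIRLEVDPNKLTVEWAAGIEQMILSQGYKAAIWLPGGLGLRWPL
>mut3
ICTVRHGCISMAWAIWTFREDLRPGEVIRLEVDPNKMTVEWANGIEQMILSQGYKAAIWDPGGLGLRCLK
>mut4
ICTARKGCISIAWAIWTFREDLRPGEVIRLEVDSNKLTVEWANGIEQMILSQGYKAAIWDPIGLTIRWPK
>mut5
ICTARKGCISMLWAIWTFREDLRPGEVIRLEVDPNKLTVEWANGIQDMILSQGYKAAIWDPQGLGLHWPK
>mut6
ICTCRKRCISMAWAIWTFREDLRPGEVIFLEVDPNKLHVEWANGIEQMILSQGYKAAKWDPGGLGLRWPK
>mut7
ICTARKGCISMAFAIWEFREDLRPGEVIRLEVDPNKLTVEWANGIEQMILSPGYKAAQWDPQGLGLRWPK
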