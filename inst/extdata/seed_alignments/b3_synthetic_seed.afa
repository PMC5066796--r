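>B3_CONS
TYDIGNRNSKFMPINGTLPSDVGKLNRLVIPKNSKAIGHHDWDNHELAVD
>mut1
TYDIGRRNSKFIPINGTLPSDVGKLNRLVIPKNSKAIGHHDWDNHALSVD
>mut2
TYDIGNRNSNFMPINGTLPSDVGKLNRLVIPKNSKAPGHHDWDNPMLAVD
>mut3
TYDIGNRTSKFMPINRDLPSDVGKLNRLVIPKNSKAIGHHDWDNHELALD
>mut4
TYIIGNRNSKFMPINGGLPSDVWKLNRLVIPKNSKRIGHHDWDNHELAVD
>mut5
TYDIGNRNSKFMPINGTLCSDVGKLNLLVIPKNSKAGGHHDWDCHELAVD
>mut6
TYDIGNRNSKFMPINGTLPGYVRKLNRLVIPKNSKAIGHHQWDNHELAVD
>mut7
TYNIGNRNSKFMPINGHLPSDVGKLKRLVIPKNSYAIGHHDWDNHELAVD
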