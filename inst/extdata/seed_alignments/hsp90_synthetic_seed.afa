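>HSP90_CONS
AQKACWAQWWMPEIGTSAELDIEDAGVAYWYSNKEIFLRERAAAMKRWALSNKLTLIGRSEFWHAEWLSQLRLGAQIYLE
>mut1
AQKACSAQRWMPEIGTSAELDIEDAGTAYWYSNKEIFLNERAAAMKRWVLSNKLTLIGRSEFWHAEWLSQERLGAQIYLE
>mut2
AQKACKAQWWMPEIDTSAELDIEDAGVAYWYSNKEIFLRERAWAMKRWNLSNKLTLIGRSEFWDAEWLSQLRLGANIYLE
>mut3
AQKACAAQWWMPEIGTSAELDIEDAGIAYWYSNKEIFLRERAAAMLRWALSNKLTRIGRSEFWHAEWLSQLGLGAQDYLE
>mut4
AQKACWAQWWMPEIGTSAELDIWDAGVAYWYSNKEIFLRERAAACKRWALSKKETLIGRSEFEHAEWLSQLRLGAAIYLE
>mut5
AQKAWIAQWWMPEIMTSAELDIEDAGVAYWQSNKEIFLRERAAAMKRWALSNKLMLIGRSEFWHAEWLSQLRLGAQIWLE
>mut6
AQKACWAQWWMPEIGTSAELDIEDAGVHMGYSNKEIFLRKPAAAMKRWDLSNKLTLIGRSEFWHAEWLSQLRLGAQIYLE
>mut7
AQKACKAQWWMPEIGTSAELDIFDAGVAYWYSNKEIFLRERAAWMKRWALSNKLTLIGRSEFWHANWLSQLRLGATIYME
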