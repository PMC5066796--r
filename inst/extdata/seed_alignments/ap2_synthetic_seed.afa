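>ERF_CONS
YRGVRQRPWGKFSAEIREDPKRGVRVWLGTFDTAEEAARARAYDRAALRMTSGKSAKLNE
>DREB_CONS
YRGVRQRPWGKFSVEIREEPKRGVRVWLGTFDTAEEAARARAYDRAALRMTSGKSAKLNE
>AP2_R1
YRGVELRPWGKSSSENRENPDRGHRHYLGTFDTNERANRARAYDRNATRMTSQKSNKLIE
>AP2_R2
YRGHRQRPWGDFFGEIEESPKEGVRVYLGWFKTAREAAEARAYDEANLEMTSGDSADLNR
>ANT_R1
YRGVELRPWGKFFTRIREAYKRQVEVWLGTFDWARENARARAHDEANLRMTFGKFAKTNE
>ANT_R2
YRGHRQRPWGDSSNEIRRGPKEGHRHWLGTFKTAERAARNRAHDRNALEMWSGKSNKLNR
>SOLOIST
YRGPFIFCWGSKASNWFNQCSFEPFPWLGMKHMQNNQQFQFQGHFQQYFRMAESAQSYVN
>ERF_VAR
YRGKRQRPWGKFSAEIREMPKRGVRVWYGTFDTAEEAARARAYDRNALRMTSGKSAKLNE
>DREB_VAR
YRGVRQRPAGKFSNGIREEPKRGVRVWLGTFDTAEERARARAYDRAALRMTSGKSAKLNE
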