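>REF_ERF_CONS
YRGVRQRPWGKFSAEIREDPKRGVRVWLGTFDTAEEAARARAYDRAALRMTSGKSAKLNE
>REF_DREB_CONS
YRGVRQRPWGKFSVEIREEPKRGVRVWLGTFDTAEEAARARAYDRAALRMTSGKSAKLNE
>REF_AP2_R1
YRGVELRPWGKSSSENRENPDRGHRHYLGTFDTNERANRARAYDRNATRMTSQKSNKLIE
>REF_AP2_R2
YRGHRQRPWGDFFGEIEESPKEGVRVYLGWFKTAREAAEARAYDEANLEMTSGDSADLNR
>REF_ANT_R1
YRGVELRPWGKFFTRIREAYKRQVEVWLGTFDWARENARARAHDEANLRMTFGKFAKTNE
>REF_ANT_R2
YRGHRQRPWGDSSNEIRRGPKEGHRHWLGTFKTAERAARNRAHDRNALEMWSGKSNKLNR
>REF_SOLOIST
YRGPFIFCWGSKASNWFNQCSFEPFPWLGMKHMQNNQQFQFQGHFQQYFRMAESAQSYVN
>REF_A1
YRGHELRPWGDSFVRIREEPKRGVRVWLGTFDTAEEAARARAYDRAALRMTSGKSAKLNE
>REF_A2
YRGVRQRPWGKFSVENEREYDEQVRVWLGTFDTAEEAARARAYDRAALRMTSGKSAKLNE
>REF_A3
YRGVRQRPWGKFSVEIREEPKRGHEHWLGWFKWNEEAARARAYDRAALRMTSGKSAKLNE
>REF_A4
YRGVRQRPWGKFSVEIREEPKRGVRVWLGTFDTARRNNENRAYDEAALRMTSGKSAKLNE
>REF_A5
YRGVRQRPWGKFSVEIREEPKRGVRVWLGTFDTAEEAARARAYDRNNTEMWFQKSAKLNE
>REF_A6
YRGVRQRPWGKFSVEIREEPKRGVRVWLGTFDTAEEAARARAYDRAALRMTSGDFNDTIR
>REF_B1
YRGGLMRPWGEIHATIREDPKRGVRVWLGTFDTAEEAARARAYDRAALRMTSGKSAKLNE
>REF_B2
YRGVRQRPWGKFSAEVLTDKELRVRVWLGTFDTAEEAARARAYDRAALRMTSGKSAKLNE
>REF_B3
YRGVRQRPWGKFSAEIREDPKRGGLGWLGAFYADEEAARARAYDRAALRMTSGKSAKLNE
>REF_B4
YRGVRQRPWGKFSAEIREDPKRGVRVWLGTFDTATTDDLDRAYDLAALRMTSGKSAKLNE
>REF_B5
YRGVRQRPWGKFSAEIREDPKRGVRVWLGTFDTAEEAARARAYDRDDSLMAHRKSAKLNE
>REF_B6
YRGVRQRPWGKFSAEIREDPKRGVRVWLGTFDTAEEAARARAYDRAALRMTSGEHDESGT
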