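>LuxR synthetic reference (AHL-binding)
QEPRQLGQQNAGAHVTRYRRIPRDPHAPFRICQPEAVEELYNRNDYGHINNRELDTNECYGGNKQNLVIFREDSGKIGCHHPAGHIVVIVNELVVNVKPVYRESFLTRQLSFHQNTSDDR
>LasR synthetic reference (AHL-binding)
QEPRALFQQVVGADVTNYAVIPCDPHAYFRICQPEAVGELYTRNAYGHIANRELRTNECYGGRKQNSVIFREDSGKIGCHHEFGEIVVIVVEQVVYRNPVYRESRLTRQLSFHQNTSDDR
>TraR synthetic reference (AHL-binding)
VEPRYLFQQVAGAHVTNYAYIPRDPHPYIRCCQPEAVGELYNRNFYGHRANRELHTNECYGGNKQNSVIFREDSGKSGLHHPFGHIVHIVNELVVNVKPVYRESRLTRQGSFHQNTSDDY
>PhzR synthetic reference (AHL-binding)
QEDRELFQLVAGAHVTNNAYDPRDRHAYKRICQPEAVGELYNRNDYGHKANRELLTNERYAGNKQNSVIFREDAGKIGCHHPFGHIVVICNEGVVNRKPVYRESRLTRQLLFHQNTSDDR
>BjaR synthetic reference (AHL-binding)
QEPRHLIQQLIGAHFTNYAYIPRDPHAYFRICQPHAVGALYNGTDYDHIENYELRTNECYGGNKQNSVIFREDSGKIGCHHPFGHIVCIVNELVRNRKPVYRESRLTRQLSFHQNTSDDR
>RpaR synthetic reference (AHL-binding)
QEPRELFQQVAGCHPFNYAYIVRDPHADFRICQPETVGELYNRNDYGHIPTRELRTNKCYGGNKQNSSIFREDSGNIGCHHPFGHIVVIVTELVVNRKNVYRESRLIRQLSFHQNTSDDR
>YenR synthetic reference (AHL-binding)
QEPRELFQPVAGGHVKNACYIPRDHHALFRICQPEAVGGLYNRNDYGHIANRELRTNEEYRGNKQNSVIFRCDSGKIGCHHPFLHICLIVNELVVNRKPVYRESRLTRQLSFHQNTSDDR
>EsaR synthetic reference (AHL-binding)
QEPRELFQQVAGAHVTNYAYIPRDPYAYFRICQPEAVGELDNRNGYGHIANRELRSNCCYGGNKPNSVIFREDSGKIGAHHGFGHIVVIVYELVVNRKPVSRESRLTRQLSFHQHISLDH
>SdiA synthetic reference (AHL-binding)
QEPRELFQQVACTHVTNYAYKPRDPHAYFRICQPEAVGELYNRNRVGTTANRELRTIECYGGNKQNSVIFLEDSGKIGKHHPFGHIVVIHNELVVNRDPVIRESRLTRFLSFHQNTSDDR
>BraR synthetic reference (AHL-binding)
QEPRELEQQVAGAHVTNYAYIGRDPHAPFRICQAEAVGVLYNRNDPGHIANRELRKNECYGGNKQNSVIVREDSGKIGCHHPFVHTVVIVSELVHNRKPVYRESRLFRQLSFHQNYSDDR
>RhlR synthetic reference (AHL-binding)
QIPRELFQQVAGAHDDNLAYIPRDPHAYFRICQPEAVGELYNRNDNGHNANRELRNNECYGGGIQNSVIFREDSIKIGCHHPFGHIVVIVVELVVNRKPVASESRLTRQLSFHQNFSDDR
>BpsR synthetic reference (AHL-binding)
QEPRELFQQVGRAHVTNYAYEPRDPHAYFRICQPEAVDELYNRNDHGHGANRLLRNNECYGGNKQNSVIFREPSGKEGCHHPFGHIVVIVNVLVVNRKPVYRESRKCRQLSFHQNTSDDA
>OryR synthetic reference (plant-responsive)
AEPEELFQQPAGAHARNYHYIPHDPYAYFRICQPETVGEMYYHSDSGRIANNKLRTNCVWHGNKQNSSIAREDRGKNGIHPPVGHIVVISNELFTCRFPDYVESILTKQLIFHTNTSDHR
>NesR synthetic reference (plant-responsive)
AQPEEKFQQPALAHATNYHYIPHDPSAYFRIIQPETVGEMYYHEDPGRIANNKLRTNCVWGGNGQVSLIAREDRGKNGCHHPHGHIVVIFNELVTTRKPVYVESISTKQLIFHTNTSDYR
>GerE synthetic reference (outgroup)
AEPKFAFTVRDQTHPKNLAYISHPCHAYPRICQSEIQHEVAHHNDYGRRPSQNLRYNENFCGNKRCSLITPYDGHKDCCHPPTARGCVICEVLYVTRVSVYRCARNTCQLSFLFNTHDFR
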