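# <localizations insequence="true" repetitions="variable"><field identifier="Position-0-0" unit="nanometer" min="0 m" max="2e-05 m" /><field identifier="Position-1-0" unit="nanometer" min="0 m" max="2e-05 m" /><field identifier="ImageNumber" unit="frame" min="0 fr" max="9999 fr" /><field identifier="Amplitude" unit="A/D count" /><field identifier="PSFWidth-0-0" unit="nanometer" /></localizations>
100.0 200.0 0 1250.5 150.2
110.0 210.0 0 980.2 148.9
500.0 500.0 1 2100.8 151.7
505.5 498.2 1 1500.0 149.3
1200.25 750.75 2 850.4 152.0
1190.0 760.5 2 1120.7 150.6
300.4 1400.9 3 990.1 147.8
310.2 1410.1 4 1010.6 149.0
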