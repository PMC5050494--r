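"id","frame","x [nm]","y [nm]","sigma [nm]","intensity [photon]","offset [photon]","bkgstd [photon]","uncertainty [nm]"
1,1,100.0,200.0,150.2,1250.5,80.1,12.3,11.2
2,1,110.0,210.0,148.9,980.2,79.5,11.8,13.4
3,2,500.0,500.0,151.7,2100.8,81.0,12.9,8.6
4,2,505.5,498.2,149.3,1500.0,80.7,12.1,10.1
5,3,1200.25,750.75,152.0,850.4,79.9,13.0,14.8
6,3,1190.0,760.5,150.6,1120.7,80.3,12.5,12.0
7,4,300.4,1400.9,147.8,990.1,80.0,11.9,13.1
8,5,310.2,1410.1,149.0,1010.6,80.2,12.2,12.9
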