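genotype,ASV,ASI,bi,Wi2,shukla,WAAS
G1,5.21,18.6,1.11,3703398,336127.5,10.8
G2,11.7,42,1.38,8528254,823486.7,18.2
G3,9.93,35.6,1.31,6997377,668852.7,12.9
G4,4.41,15.8,0.98,2522387,216833.5,8.18
G5,5.55,19.9,0.88,2844030,249322.6,8.08
G6,11,39.5,0.86,8883773,859397.8,21.4
G7,9.72,34.8,1.32,6471572,615741,16.9
G8,4.59,16.5,1.11,3814730,347373.2,9.51
G9,8.34,29.9,1.18,6931041,662152.1,16.9
G10,6.8,24.4,1.03,5714189,539237.8,15.1
G11,3.26,11.7,0.90,3696320,335412.6,8.08
G12,2.26,8.09,0.91,2709855,235769.7,4.3
G13,11.3,40.7,1.10,9553098,927006.3,18.7
G14,8.73,31.3,1.16,5181614,485442.2,12.6
G15,11,39.4,0.77,12951290,1270258,24.7
G16,8.26,29.6,1.21,10549380,1027641,15.9
G17,10.7,38.3,0.82,8317319,802180.2,16.9
G18,11.1,39.8,0.72,8019729,772120.5,18.3
G19,13.6,48.8,0.54,11113063,1084579,19.2
G20,12,42.9,0.71,14277088,1404177,20.9
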