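SYNTH_SET_01	synthetic gene set	G0561|-1	G0321|-1	G1177|+1	G1098|-1	G1252|+1	G1170|-1	G0634|-1	G0049|-1	G1152|+1	G1327|+1	G0024|-1	G1863|-1	G0356|-1	G1625|-1	G0165|-1	G0622|-1	G1556|-1	G0410|+1	G1906|-1	G1903|+1	G0899|-1	G1321|-1	G0601|-1	G1307|-1	G0932|+1	G0997|-1	G0621|+1	G1541|+1	G1236|+1	G1954|-1
SYNTH_SET_02	synthetic gene set	G0626|+1	G0262|-1	G0390|-1	G0130|-1	G1396|+1	G1027|-1	G0374|-1	G1429|-1	G0770|-1	G1015|-1	G1894|+1	G0698|-1	G0650|+1	G0040|-1	G0517|-1	G0033|+1	G0945|-1	G0103|+1	G1252|-1	G0109|+1	G1002|-1	G1353|+1	G1693|-1	G0076|-1	G0980|+1	G1801|+1	G1515|+1	G1571|-1	G0733|+1	G0016|-1
SYNTH_SET_03	synthetic gene set	G0720|+1	G1782|+1	G0060|+1	G1309|+1	G0849|+1	G1644|+1	G0969|-1	G0377|+1	G1877|-1	G0638|-1	G0427|+1	G0442|-1	G1136|-1	G0584|+1	G1995|+1	G0951|-1	G1958|+1	G1537|-1	G1165|+1	G1742|-1	G1925|-1	G1992|+1	G0311|-1	G0912|+1	G0474|-1	G0811|-1	G1578|-1	G0042|-1	G0760|-1	G1889|-1
SYNTH_SET_04	synthetic gene set	G0607|-1	G1542|+1	G1876|-1	G0764|-1	G0783|+1	G0546|-1	G0426|+1	G0471|+1	G0188|+1	G0254|+1	G0268|-1	G0640|-1	G1434|-1	G0041|-1	G1217|+1	G1602|+1	G0824|+1	G0664|-1	G1122|-1	G0537|+1	G0348|+1	G0107|+1	G0317|+1	G1038|-1	G0162|-1	G0636|-1	G0706|+1	G1631|+1	G1568|+1	G1947|-1
SYNTH_SET_05	synthetic gene set	G1204|-1	G0868|+1	G0212|+1	G1611|+1	G0201|-1	G1425|-1	G0062|+1	G1293|-1	G1406|-1	G1148|+1	G1087|+1	G0561|+1	G0573|+1	G1652|+1	G1793|+1	G1937|-1	G1953|+1	G0540|+1	G0002|-1	G0671|-1	G1672|+1	G1151|+1	G1232|+1	G0771|-1	G0741|+1	G0269|-1	G1036|-1	G0705|-1	G0670|+1	G1587|+1
SYNTH_SET_06	synthetic gene set	G1126|-1	G0171|-1	G0489|+1	G1686|+1	G0922|+1	G0694|+1	G1846|+1	G1591|-1	G1590|+1	G1023|-1	G1850|-1	G1709|-1	G1445|-1	G1579|+1	G1231|+1	G1109|-1	G1954|-1	G0153|-1	G1894|+1	G0961|+1	G1934|+1	G0240|-1	G0049|+1	G1163|+1	G0156|+1	G0274|+1	G1991|-1	G1250|+1	G0762|-1	G0170|-1
SYNTH_SET_07	synthetic gene set	G1238|-1	G0985|+1	G0438|+1	G1851|-1	G0625|-1	G0542|-1	G0699|+1	G1493|-1	G1900|-1	G0917|-1	G0966|+1	G1583|-1	G1129|+1	G1226|-1	G0088|+1	G1394|+1	G1975|-1	G0391|-1	G0398|+1	G0268|+1	G1717|-1	G0819|+1	G1546|-1	G1145|-1	G1625|-1	G0037|-1	G0706|-1	G0163|+1	G1442|+1	G1819|-1
SYNTH_SET_08	synthetic gene set	G1797|+1	G0159|+1	G0928|-1	G0978|+1	G0935|-1	G0653|-1	G1402|-1	G1566|+1	G1078|+1	G0514|-1	G0540|+1	G0387|-1	G0929|+1	G1647|-1	G0989|-1	G1236|+1	G0747|+1	G1289|-1	G1846|+1	G1162|+1	G1735|-1	G0627|-1	G1618|-1	G1433|-1	G0620|-1	G0202|+1	G0073|-1	G1683|+1	G0335|+1	G1070|+1
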