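Model,Scenario,Region,Variable,Unit,2000,2001,2002,2003,2004,2005,2006,2007,2008,2009,2010,2011,2012,2013,2014,2015,2016,2017,2018,2019,2020,2021,2022,2023,2024,2025,2026,2027,2028,2029,2030,2031,2032,2033,2034,2035,2036,2037,2038,2039,2040,2041,2042,2043,2044,2045,2046,2047,2048,2049,2050,2051,2052,2053,2054,2055,2056,2057,2058,2059,2060,2061,2062,2063,2064,2065,2066,2067,2068,2069,2070,2071,2072,2073,2074,2075,2076,2077,2078,2079,2080,2081,2082,2083,2084,2085,2086,2087,2088,2089,2090,2091,2092,2093,2094,2095,2096,2097,2098,2099,2100
ch4margin,mitigation-1p5C,World,Emissions|CO2,Gt CO2/yr,30,30.304499999999997,30.616000000000003,30.9315,31.248000000000001,31.5625,31.872,32.173499999999997,32.463999999999999,32.740499999999997,33,33.240499999999997,33.464000000000006,33.673500000000004,33.872,34.0625,34.248000000000005,34.4315,34.616,34.804499999999997,35,33.284999999999997,31.654034999999997,30.102987284999994,28.627940908034997,27.225171803541279,25.891138385167753,24.622472604294533,23.4159714466841,22.268588845796575,21.177427992352548,20.149218923124455,19.100731083732061,18.038724064230145,16.969957454673459,15.901190845116778,14.839183825614858,13.790695986222469,12.762486916994375,11.761316207985336,10.793943449250122,9.8671282308434964,8.9876301428202225,8.158042361246677,7.3726119016876854,6.6255791134457027,5.9111843458231732,5.2236679481225492,4.5572702696462795,3.9062316596968101,3.2647924675765929,2.6271930425880772,1.9876737340337109,1.3404748912159423,0.6798368634372226,0,-0.26855418381344309,-0.54053223593964339,-0.81540740740740747,-1.0926529492455419,-1.3717421124828533,-1.6521481481481484,-1.9333443072702332,-2.2148038408779152,-2.4960000000000004,-2.7764060356652949,-3.055495198902606,-3.3327407407407406,-3.6076159122085047,-3.8795939643347053,-4.1481481481481488,-4.4127517146776407,-4.6728779149519886,-4.9280000000000017,-5.1775912208504797,-5.4211248285322355,-5.658074074074074,-5.8879122085048019,-6.1101344307270233,-6.3247407407407401,-6.5322359396433471,-6.733146776406036,-6.9279999999999999,-7.1173223593964341,-7.3016406035665291,-7.481481481481481,-7.6573717421124838,-7.8298381344307266,-7.9994074074074062,-8.1666063100137158,-8.3319615912208498,-8.4960000000000004,-8.6592482853223594,-8.8222331961591234,-8.9854814814814823,-9.1495198902606312,-9.3148751714677651,-9.4820740740740721,-9.6516433470507561,-9.824109739368998,-10
ch4margin,mitigation-1p5C,World,Emissions|CH4|Livestock,Mt CH4/yr,102.63929618768329,103.70244134897359,104.82275659824047,105.97574046920822,107.13689149560119,108.28170821114371,109.38568914956012,110.42433284457479,111.37313782991203,112.20760263929618,112.90322580645162,113.44367302052785,113.84527859237539,114.1325439882698,114.3299706744868,114.46206011730204,114.5533137829912,114.62823313782991,114.71131964809385,114.82707478005865,115,113.48066666666666,111.92533333333334,110.33799999999999,108.72266666666667,107.08333333333334,105.42400000000001,103.74866666666667,102.06133333333334,100.366,98.666666666666657,96.967333333333329,95.272000000000006,93.584666666666678,91.909333333333322,90.25,88.610666666666674,86.995333333333335,85.408000000000001,83.852666666666678,82.333333333333343,80.853999999999999,79.418666666666667,78.031333333333336,76.695999999999998,75.416666666666657,74.197333333333319,73.041999999999987,71.954666666666654,70.939333333333323,70,69.12375999999999,68.294080000000008,67.509519999999981,66.768640000000005,66.070000000000007,65.41216,64.793679999999995,64.213120000000004,63.669039999999988,63.159999999999989,62.684560000000005,62.241280000000003,61.828720000000004,61.445439999999998,61.089999999999996,60.760959999999997,60.456880000000005,60.176320000000004,59.917840000000005,59.68,59.461359999999999,59.260480000000001,59.075919999999996,58.906240000000004,58.75,58.605759999999997,58.472079999999998,58.347520000000003,58.230639999999994,58.11999999999999,58.014160000000004,57.911679999999997,57.811119999999995,57.711040000000004,57.609999999999999,57.50656,57.399279999999997,57.286720000000003,57.167439999999999,57.039999999999999,56.90296,56.75488,56.594319999999996,56.419840000000001,56.230000000000004,56.023359999999997,55.798479999999998,55.553919999999998,55.288239999999995,55
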