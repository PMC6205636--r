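measure,y2007,y2008,y2009,y2010,y2011,y2012,y2013,y2014,y2015,y2016,total
total_funding,1878891,2580074,2439936,2629582,2514475,2144056,2091740,1951594,2029877,1977657,22237882
sub_awards,189820,257571,240180,242394,215096,166268,151233,141020,150218,164171,1917972
ec_capital,15925,21868,20680,21960,20851,30868,22123,14640,14285,5343,188541
ec_vehicles,9267,12725,12034,12969,12402,10575,16833,10783,10056,10675,118319
ec_lab,33686,51924,55154,51891,42857,42882,49381,23272,20377,16334,387759
ec_arv,293509,385787,315336,315757,297154,254459,279759,325836,337774,380344,3185715
total_nec,1336684,1850198,1796552,1984611,1926116,1639005,1572411,1436043,1497166,1400791,16439576
A,352687,487936,473635,523194,509869,434364,415951,379624,392446,368987,4338694
B,333567,463036,448540,499938,485966,410058,397313,363278,372605,351542,4125841
C,274318,380170,369448,409004,397857,337271,322466,294823,305645,286295,3377297
ASSUMED_20,231119,320532,311596,343414,331761,283334,271523,247796,260022,242478,2843575
ASSUMED_15,193178,267869,260510,285367,273964,236295,225220,205052,217596,201757,2366807
ASSUMED_10,151788,210418,204779,222043,210911,184980,174707,158423,171314,157334,1846697
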