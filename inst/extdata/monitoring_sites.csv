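site,lat,lon,method,first_year,last_year,mean_occupancy,mean_units
Alavus,62.801,23.577,nestbox,1995,2011,0.12,130
Anjalankoski,60.724,26.982,nestbox,1999,2005,0.08,161
Kauhava,63.091,23.017,nestbox,2002,2015,0.10,357
Luoto,63.809,22.785,nestbox,1993,2011,0.18,189
Vaasa,63.045,21.654,nestbox,1992,2014,0.16,211
Mynamaki,60.664,22.194,nestbox,1992,2003,0.05,113
Sauvo,60.341,22.723,nestbox,1992,2003,0.08,96
Muurla-Lohja,60.358,23.705,pellet,2001,2011,0.59,69
Virrat-Keuruu,62.322,24.119,pellet,1988,2012,0.60,82
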