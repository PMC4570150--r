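name	tier	country	region	mesh_listed	no_region
United States	country	United States		1	0
USA	country	United States		1	0
U.S.A.	country	United States		1	0
Italy	country	Italy		1	0
China	country	China		1	0
United Kingdom	country	United Kingdom		1	0
UK	country	United Kingdom		1	0
France	country	France		1	0
Serbia	country	Serbia		1	0
Andorra	country	Andorra		0	1
Massachusetts	admin1	United States	Massachusetts	0	0
MA	state_code	United States	Massachusetts	0	0
New York	admin1	United States	New York	0	0
NY	state_code	United States	New York	0	0
Regione Lombardia	admin1	Italy	Regione Lombardia	0	0
Lombardy	admin1	Italy	Regione Lombardia	0	0
Milan	city	Italy	Regione Lombardia	0	0
Quangdong sheng	admin1	China	Quangdong sheng	0	0
Shantou	city	China	Quangdong sheng	0	0
England	admin1	United Kingdom	England	0	0
Scotland	admin1	United Kingdom	Scotland	0	0
Wales	admin1	United Kingdom	Wales	0	0
Yorkshire	admin2	United Kingdom	England	0	0
Glasgow	city	United Kingdom	Scotland	0	0
Edinburgh	capital	United Kingdom	Scotland	0	0
Grad Beograd	admin1	Serbia	Grad Beograd	0	0
Belgrade	capital	Serbia	Grad Beograd	0	0
Yugoslavia	historical_country			0	0
USSR	historical_country			0	0
Pacific Ocean	water_body			0	0
Atlantic Ocean	water_body			0	0
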