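name	alpha3
Albania	ALB
Algeria	DZA
Andorra	AND
Armenia	ARM
Austria	AUT
Belarus	BLR
Belgium	BEL
Bosnia and Herzegovina	BIH
Bulgaria	BGR
China	CHN
Croatia	HRV
Cyprus	CYP
Czech Republic	CZE
Czechia	CZE
Democratic Republic of the Congo	COD
Denmark	DNK
Egypt	EGY
Eritrea	ERI
Estonia	EST
Ethiopia	ETH
Finland	FIN
France	FRA
Germany	DEU
Greece	GRC
Hungary	HUN
Iceland	ISL
Ireland	IRL
Israel	ISR
Italy	ITA
Jordan	JOR
Kenya	KEN
Korea	KOR
South Korea	KOR
Republic of Korea	KOR
Latvia	LVA
Lebanon	LBN
Libya	LBY
Liechtenstein	LIE
Lithuania	LTU
Luxembourg	LUX
Macedonia	MKD
Malta	MLT
Mexico	MEX
Moldova	MDA
Republic of Moldova	MDA
Montenegro	MNE
Morocco	MAR
Netherlands	NLD
North Macedonia	MKD
Norway	NOR
Poland	POL
Portugal	PRT
Romania	ROU
Russia	RUS
Russian Federation	RUS
Rwanda	RWA
Serbia	SRB
Slovakia	SVK
Slovenia	SVN
Spain	ESP
Sweden	SWE
Switzerland	CHE
Syria	SYR
Syrian Arab Republic	SYR
Tanzania	TZA
Tunisia	TUN
Turkey	TUR
Türkiye	TUR
Uganda	UGA
Ukraine	UKR
United Kingdom	GBR
UK	GBR
United States	USA
USA	USA
Yemen	YEM
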