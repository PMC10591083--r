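taxon	priority
Brassica deserti Danin & Hedge	high
Brassica desnottesii Emb. & Maire	high
Brassica dimorpha Coss. & Durieu	high
Brassica elongata Ehrh.	high
Brassica fruticulosa Cirillo	high
Brassica gravinae Ten.	high
Brassica hilarionis Post	high
Brassica insularis Moris	high
Brassica maurorum Durieu	high
Brassica montana Pourr.	high
Brassica repanda (Willd.) DC.	high
Brassica souliei Batt. subsp. amplexicaulis (Desf.) Greuter & Burdet	high
Brassica souliei Batt. subsp. souliei Batt.	high
Descurainia sophia (L.) Webb ex Prantl	high
Diplotaxis siifolia Kunze	high
Enarthrocarpus lyratus (Forssk.) DC.	high
Erucastrum gallicum (Willd.) O. E. Schulz	high
Rorippa islandica (Oeder) Borb	high
Brassica bourgeaui (Webb ex Christ) Kuntze	medium
Brassica cretica Lam.	medium
Brassica incana Ten.	medium
Brassica nigra (L.) W. D. J. Koch	medium
Capsella bursa-pastoris (L.) Medik.	medium
Diplotaxis acris (Forsk.) Boiss.	medium
Diplotaxis catholica (L.) DC.	medium
Diplotaxis erucoides (L.) DC.	medium
Diplotaxis harra (Forssk.) Boiss.	medium
Diplotaxis muralis (L.) DC.	medium
Diplotaxis tenuifolia (L.) DC.	medium
Diplotaxis viminea (L.) DC.	medium
Moricandia arvensis (L.) DC.	medium
Moricandia nitens (Viv.) E. A. Durand & Barratte	medium
Rapistrum rugosum (L.) All.	medium
Sinapis arvensis L.	medium
Sinapis pubescens L.	medium
Brassica tournefortii Gouan	low
Eruca vesicaria (L.) Cav.	low
Hirschfeldia incana (L.) Lagr.-Foss.	low
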