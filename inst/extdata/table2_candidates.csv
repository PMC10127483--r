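year_category,material_id,material_class,gene_id,chromosome
2018-2019,00344,OE,GRMZM2G012891,Chr7
2018-2019,01299,OE,GRMZM2G093195,Chr9
2018-2019,01924,OE,GRMZM2G328785,Chr6
2018-2019,02454,OE,GRMZM2G333183,Chr10
2018-2019,02900,OE,GRMZM2G164475,Chr3
2018-2019,02916,OE,GRMZM2G142409,Chr6
2018-2019,03824,OE,GRMZM2G178795,Chr4
2018-2019,80072,Cas9,GRMZM2G134708_T01,Chr4
2018-2019,90084,Cas9,GRMZM2G077278_T01,Chr6
2018-2019,91078,OE,AT4G17870.1,Chr4 in Arabidopsis
2018,01627,OE,GRMZM2G123387,Chr2
2018,01835,OE,GRMZM2G150796,Chr7
2018,01875,OE,GRMZM2G360589,Chr5
2018,02157,OE,GRMZM2G111906,Chr6
2018,02840,OE,GRMZM2G470942,Chr8
2018,91047,OE,GRMZM2G446858,Chr3
2019,00725,OE,GRMZM2G009913,Chr5
2019,02241,OE,GRMZM2G034622,Chr6
2019,02445,OE,GRMZM2G312521,Chr4
2019,02479,OE,GRMZM2G414460,Chr7
2019,02926,OE,GRMZM2G347361,Chr2
2019,03522,OE,GRMZM2G145879,Chr6
2019,03773,OE,GRMZM2G479318,Chr1
2019,03796,OE,MGG_05056,Chr3 in Pyricularia oryzae
2019,03803,OE,MGG_06559,Chr4 in Pyricularia oryzae
2019,03813,OE,MGG_10492,Chr2 in Pyricularia oryzae
2019,80017,Cas9,GRMZM2G368838_T01,Chr2
2019,80024,Cas9,GRMZM2G090435_T01,Chr5
2019,80027,Cas9,GRMZM2G014136_T01,Chr3
2019,80035,Cas9,GRMZM2G130442_T01,Chr4
2019,80051,Cas9,GRMZM2G126505_T01,Chr4
2019,80067,Cas9,GRMZM2G099425_T01,Chr2
2019,80073,Cas9,GRMZM2G090241_T01,Chr4
2019,80080,Cas9,GRMZM2G004483_T01,Chr9
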