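"taxon","moss","dead_wood","litter"
"Brachychthoniidae spp.",134471,10619,2682
"Cosmochthonius lanatus",0,40,0
"Eniochthonius minutissimus",421610,164559,48119
"Hypochthonius rufulus",68605,8057,17728
"Microtritia minima",3179,25504,3398
"Phthiracaridae spp.",536127,298994,75466
"Rhysotritia duplicata",0,125,0
"Camisia spinifer",2100,0,0
"Nanhermannia nana",1984,766,1814
"Nothrus palustris",2533,1385,5723
"Nothrus silvestris",42847,2647,10125
"Platynothrus peltifer",114433,19862,112682
"Adoristes ovatus",248111,21508,66936
"Achipteria coleoptrata",37850,8255,34428
"Achipteria nitens",38587,6592,24612
"Astegistes pilosus",2033,2102,664
"Autogneta longilamellata",152172,76903,91
"Banksinoma lanceata",41800,27520,0
"Berniella sigma",15921,371,362
"Carabodes spp.",272400,56007,24443
"Cepheus cepheiformis",90862,5968,17417
"Ceratoppia bipilis",19922,1098,340
"Ceratozetes cf gracilis",2000,0,214
"Chamobates borealis",19600,250,0
"Chamobates cuspidatus",509359,19014,46862
"Chamobates subglobulus",1200,643,141
"Cultroribula bicultrata",2127,2066,204
"Cymberemaeus cymba",20800,1407,2528
"Damaeus gracilipes",72100,647,118
"Damaeus onustus",211229,17771,19894
"Dissorhina ornata",28634,885,453
"Dometorina plantivaga",18035,375,48
"Eupelops plicatus",149786,5868,5851
"Euzetes globulus",20084,7859,15828
"Galumna lanceata",0,2092,498
"Hermannia gibba",1024849,156063,14109
"Liacarus coracinus",68472,51217,635
"Liacarus subterraneus",0,40,0
"Licneremaeus licnophorus",30788,267,0
"Liebstadia longior",370,40,0
"Liebstadia similis",1833,220,531
"Metabelba pulverosa",81211,3944,42291
"Medioppia subpectinata",1063064,250431,120330
"Microppia minus",24083,15823,1181
"Multioppia laniseta",111423,70901,50008
"Oppia denticulata",4600,3765,0
"Oppiella falcata",218719,8480,108
"Oppiella nova",191072,282102,3105
"Oribatella quadricornuta",12430,564,642
"Oribatula tibialis",3033,5915,144
"Pantelozetes paolii",0,222,1957
"Peloptulus phaenotus",200,0,0
"Poroliodes farinosus",40972,3001,790
"Punctoribates punctum",200,125,0
"Quadroppia quadricarinata",1139077,225312,7097
"Scapheremaeus palustris",1000,0,0
"Scheloribates laevigatus",47006,4973,1620
"Suctobelbidae spp.",494987,66672,39185
"Tectocepheus spp.",2399116,450593,28453
"Xenillus clypeator",14969,3515,1054
"Zygoribatula exilis",445671,29091,1531
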