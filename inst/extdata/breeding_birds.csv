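order,species,buffer_m,conservation_score,collision,disturbance,barrier,habitat_change,summed_sensitivity,national_pairs,pairs_0_5pct,pairs_0_1pct
Accipitriformes,Accipiter gentilis,500,2,2,0,1,0,3,500,3,1
Accipitriformes,Accipiter nisus,500,1,2,0,1,0,3,4000,20,4
Accipitriformes,Aquila chrysaetos,2000,3,2,0,1,0,3,1,1,1
Accipitriformes,Buteo buteo,1000,1,2,0,1,0,3,6000,30,6
Accipitriformes,Circus aeruginosus,1000,1,2,0,1,0,3,3500,18,4
Accipitriformes,Circus cyaneus,1000,3,2,0,1,0,3,1,1,1
Accipitriformes,Circus pygargus,1000,3,2,0,1,0,3,300,2,1
Accipitriformes,Clanga clanga,2000,3,2,0,1,0,3,1,1,1
Accipitriformes,Clanga pomarina,2000,2,2,0,1,0,3,1900,10,2
Accipitriformes,Haliaeetus albicilla,2000,2,2,0,1,0,3,120,1,1
Accipitriformes,Milvus migrans,1000,3,2,0,1,0,3,40,1,1
Accipitriformes,Milvus milvus,1000,3,2,0,1,0,3,20,1,1
Accipitriformes,Pandion haliaetus,1000,3,2,0,1,0,3,25,1,1
Accipitriformes,Pernis apivorus,1000,2,2,0,1,0,3,1000,5,1
Anseriformes,Aythya ferina,500,2,1,1,0,0,2,3000,15,3
Anseriformes,Anas clypeata,500,2,1,1,0,0,2,200,1,1
Anseriformes,Anas penelope,500,2,1,1,0,0,2,5,1,1
Anseriformes,Anas strepera,500,3,1,1,0,0,2,250,2,1
Anseriformes,Anser anser,500,2,1,1,0,0,2,200,1,1
Anseriformes,Cygnus cygnus,500,2,1,1,0,0,2,300,2,1
Anseriformes,Mergus merganser,500,2,1,1,0,0,2,1000,5,1
Caprimulgiformes,Caprimulgus europaeus,200,1,1,0,0,0,1,4000,20,4
Charadriiformes,Calidris alpina,500,3,2,0,0,0,2,5,1,1
Charadriiformes,Chlidonias hybridus,1000,3,2,0,1,0,3,50,1,1
Charadriiformes,Chlidonias leucopterus,1000,3,2,0,1,0,3,100,1,1
Charadriiformes,Chlidonias niger,1000,3,2,0,1,0,3,3000,15,3
Charadriiformes,Gallinago gallinago,500,1,1,0,0,0,1,10000,50,10
Charadriiformes,Gallinago media,500,3,2,0,0,0,2,100,1,1
Charadriiformes,Larus argentatus,1000,2,2,0,1,0,3,300,2,1
Charadriiformes,Larus cachinnans,1000,1,2,0,1,0,3,100,1,1
Charadriiformes,Larus canus,1000,1,2,0,1,0,3,300,2,1
Charadriiformes,Larus minutus,1000,2,2,0,1,0,3,50,1,1
Charadriiformes,Larus ridibundus,1000,1,2,0,1,0,3,30000,150,30
Charadriiformes,Limosa limosa,500,3,2,0,0,0,2,250,2,1
Charadriiformes,Numenius arquata,500,3,2,0,0,0,2,50,1,1
Charadriiformes,Philomachus pugnax,500,3,2,0,0,0,2,200,1,1
Charadriiformes,Pluvialis apricaria,500,3,2,0,0,0,2,40,1,1
Charadriiformes,Sterna hirundo,1000,2,2,0,1,0,3,2000,10,2
Charadriiformes,Sternula albifrons,1000,3,2,0,1,0,3,200,1,1
Charadriiformes,Tringa glareola,500,3,2,0,0,0,2,100,1,1
Charadriiformes,Tringa totanus,500,3,2,0,0,0,2,400,2,1
Charadriiformes,Vanellus vanellus,500,1,2,0,0,0,2,10000,50,10
Ciconiiformes,Ardea alba,500,2,2,1,0,0,3,50,1,1
Ciconiiformes,Ardea cinerea,500,1,2,1,0,0,3,3000,15,3
Ciconiiformes,Ciconia ciconia,500,1,2,1,0,0,3,20000,100,20
Ciconiiformes,Botaurus stellariss,500,2,1,1,0,0,2,1500,8,2
Ciconiiformes,Ciconia nigra,2000,3,2,1,0,1,4,600,3,1
Ciconiiformes,Ixobrychus minutus,1000,2,1,1,0,0,2,30,1,1
Columbiformes,Columba oenas,500,2,2,0,0,0,2,500,3,1
Columbiformes,Columba palumbus,100,1,0,0,0,0,0,60000,300,60
Columbiformes,Streptopelia turtur,500,2,2,0,0,0,2,2000,10,2
Coraciiformes,Coracias garrulus,500,3,1,0,0,0,1,10,1,1
Falconiformes,Falco columbarius,500,3,2,0,0,0,2,5,1,1
Falconiformes,Falco peregrinus,1000,3,2,0,0,0,2,1,1,1
Falconiformes,Falco subbuteo,1000,2,2,0,1,0,3,700,4,1
Falconiformes,Falco tinnunculus,1000,3,2,0,1,0,3,200,1,1
Galliformes,Lyrurus tetrix,1000,2,0,0,0,0,0,1500,8,2
Gaviiformes,Gavia arctica,500,3,1,1,0,0,2,7,1,1
Gruiformes,Crex crex,500,2,0,0,0,1,1,23000,115,23
Gruiformes,Grus grus,2000,2,0,2,0,0,2,5000,25,5
Passeriformes,Acrocephalus paludicola,500,3,1,0,0,0,1,100,1,1
Passeriformes,Corvus frugilegus,1000,2,2,0,1,0,3,30000,150,30
Passeriformes,Emberiza hortulana,500,2,1,0,0,0,1,60,1,1
Passeriformes,Luscinia svecica,500,2,1,0,0,0,1,200,1,1
Podicipediformes,Podiceps auritus,500,3,1,1,0,0,2,5,1,1
Podicipediformes,Podiceps cristatus,500,1,1,1,0,0,2,15000,75,15
Strigiformes,Apus apus,1000,3,1,0,0,0,1,20,1,1
Strigiformes,Asio flammeus,500,3,1,0,0,0,1,30,1,1
Strigiformes,Asio otus,500,1,1,0,0,0,1,3000,15,3
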