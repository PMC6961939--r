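order,species,buffer_m,conservation_score,collision,disturbance,barrier,habitat_change,summed_sensitivity,minimal_abundance,significant_abundance
Accipitriformes,Buteo buteo,1000,1,2,0,1,0,3,10,15
Accipitriformes,Haliaeetus albicilla,2000,1,2,0,1,0,3,5,10
Accipitriformes,Clanga pomarina,2000,2,2,0,1,0,3,3,8
Anseriformes,Aythya fuligula,500,2,1,1,0,0,2,100,500
Anseriformes,Anas penelope,500,2,1,1,0,0,2,200,500
Anseriformes,Anas platyrhynchos,500,1,1,1,0,0,2,300,500
Anseriformes,Anas strepera,500,1,1,1,0,0,2,20,50
Anseriformes,Anser albifrons,500,1,1,1,0,0,2,500,1000
Anseriformes,Anser anser,500,1,1,1,0,0,2,10,40
Anseriformes,Anser erythropus,500,3,1,1,0,0,2,1,5
Anseriformes,Anser fabalis,500,1,1,1,0,0,2,300,1000
Anseriformes,Branta leucopsis,500,1,1,1,0,0,2,20,100
Anseriformes,Bucephala clangula,500,1,1,1,0,0,2,200,1000
Anseriformes,Cygnus cygnus,500,1,1,1,0,0,2,20,50
Anseriformes,Cygnus columbianus,500,3,1,1,0,0,2,10,20
Anseriformes,Cygnus olor,500,1,1,1,0,0,2,50,100
Anseriformes,Melanitta fusca,500,2,1,1,0,0,2,100,200
Anseriformes,Mergus albellus,500,1,1,1,0,0,2,20,50
Anseriformes,Mergus merganser,500,1,1,1,0,0,2,30,80
Ardeidae,Ardea cinerea,500,1,1,0,1,0,2,20,50
Charadriiformes,Calidris alpina,500,1,1,0,0,0,1,20,50
Charadriiformes,Chlidonias hybridus,1000,3,1,0,1,0,2,20,100
Charadriiformes,Chlidonias leucopterus,1000,3,1,0,1,0,2,20,100
Charadriiformes,Chlidonias niger,1000,2,1,0,1,0,2,20,50
Charadriiformes,Gallinago gallinago,500,1,1,0,0,0,1,30,50
Charadriiformes,Larus cachinnans,1000,1,1,0,1,0,2,50,100
Charadriiformes,Larus canus,1000,1,1,0,1,0,2,300,500
Charadriiformes,Larus marinus,1000,1,1,0,1,0,2,10,20
Charadriiformes,Larus minutus,1000,1,1,0,1,0,2,50,150
Charadriiformes,Limosa limosa,500,2,1,0,0,0,1,5,15
Charadriiformes,Numenius arquata,500,2,1,0,0,0,1,10,100
Charadriiformes,Philomachus pugnax,500,3,1,0,0,0,1,50,100
Charadriiformes,Pluvialis apricaria,500,1,1,0,0,0,1,100,500
Charadriiformes,Vanellus vanellus,500,2,1,0,0,0,1,100,500
Ciconiiformes,Ciconia ciconia,500,1,2,1,0,0,3,50,100
Ciconiiformes,Ciconia nigra,2000,2,2,1,0,1,4,4,10
Ciconiiformes,Egretta alba,500,1,2,1,0,0,3,50,100
Columbiformes,Columba palumbus,100,1,2,0,0,0,2,50,100
Gruiformes,Fulica atra,500,1,1,1,0,0,2,100,500
Gruiformes,Grus grus,2000,1,0,2,2,0,4,50,200
Passeriformes,Corvus frugilegus,1000,1,1,0,0,0,1,200,500
Pelecaniformes,Phalacrocorax carbo,500,1,1,0,0,0,1,200,500
Podicipedidae,Podiceps cristatus,500,1,1,1,0,0,2,20,50
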