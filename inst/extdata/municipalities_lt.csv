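municipality,area_km2,installed_mw,wind_density_wm2,grid_capacity_mw,special_plan,planned_mw,forest_pct,index_printed,priority_printed,estimated_pct,high_pct,medium_pct,low_pct
Akmene,844,0,132,70,1,63,32.4,0.7,2,63.1,22.9,12.5,27.7
Alytus,1443,0,148,150,0,,25.1,0.75,2,68.9,34.1,15.0,19.7
Anyksciai,1764,7.5,120,60,1,,32.7,0.6,2,55.2,33.1,9.6,12.5
Birstonas,122,0,167,0,0,,47.1,0.5,3,72.0,0.0,64.3,7.7
Birzai,1476,0,90,100,0,0.03,27.2,0.85,2,86.9,39.8,27.1,20.1
Druskininkai,453,0,66,70,0,,69.1,0.3,3,52.6,0.0,31.7,20.9
Elektrenai,509,0,167,70,0,,32.8,0.75,2,66.3,41.7,15.3,9.3
Ignalina,1441,0,89,100,0,,36.4,0.65,2,61.6,40.8,13.7,7.0
Jonava,943,0,137,130,1,41,41.8,0.95,2,56.5,20.9,8.6,27.0
Joniskis,1152,0,91,70,0,,20.2,0.5,3,62.9,0.0,20.4,42.6
Jurbarkas,1506,24,157,60,1,89.8,38.1,1.15,1,62.4,28.2,11.8,22.4
Kaisiadorys,1088,6,167,125,1,48.93,32.8,1.3,1,79.6,45.3,20.8,13.5
Kalvarija,440,0,190,0,1,14.4,14.2,1.65,1,91.4,67.4,7.5,16.5
Kaunas,1652,0,167,295,0,51.27,32.5,1.35,1,81.5,45.8,17.4,18.3
Kazlu Ruda,555,0,190,150,0,,60,0.9,2,22.0,5.1,2.6,14.3
Kedainiai,1677,0,90,110,0,120.1,25.1,0.95,2,68.5,37.6,8.7,22.2
Kelme,1705,0,91,60,1,100.8,31.8,0.8,2,53.0,22.0,8.6,22.4
Klaipeda,1438,0,342,60,0,69.19,26.4,1.3,1,87.5,43.3,16.4,27.7
Kretinga,989,106.56,342,60,1,39.61,34.9,1.4,1,80.2,25.0,13.4,41.8
Kupiskis,1080,0,90,100,0,,29.5,0.75,2,61.4,39.0,7.4,15.1
Lazdijai,1306,6,148,150,0,1.55,35.9,0.75,2,48.3,33.0,3.1,12.3
Marijampole,755,0,190,50,0,2,15.4,1.45,1,59.4,36.3,11.6,11.5
Mazeikiai,1220,45.6,132,10,1,22.2,29.5,0.8,2,58.6,21.2,10.7,26.7
Moletai,1367,0,66,70,0,,31.5,0.4,3,62.9,0.0,41.8,21.1
Pagegiai,90,77.5,342,50,1,100.83,17.4,1.6,1,73.5,56.3,8.6,8.6
Pakruojis,535,6,91,50,1,22,19.8,0.8,2,79.9,27.3,20.2,32.3
Panevezys,1315,0,120,140,0,0.05,34.9,0.75,2,67.6,34.8,12.8,20.0
Pasvalys,79,0,90,100,0,,17,0.75,2,89.2,19.8,38.5,30.9
Plunge,2227,0,149,60,0,,36.5,0.4,3,79.2,0.0,46.8,32.3
Prienai,1289,0,167,150,0,5,27.7,1.2,1,56.7,24.3,13.0,19.3
Radviliskis,1105,0,91,50,0,,25.9,0.5,3,54.2,0.0,25.3,28.9
Raseiniai,1032,0,157,60,0,68.5,23.8,0.95,2,58.4,25.0,10.3,23.1
Rietavas,1634,0,220,60,0,,54.1,0.65,2,56.4,12.4,9.8,34.2
Rokiskis,1573,0,90,100,0,15.15,29.3,0.85,2,68.6,34.8,9.5,24.2
Skuodas,586,0,132,0,0,8.2,10.9,0.35,3,64.9,0.0,12.6,52.3
Sakiai,1806,0,190,50,1,88.5,23,1.25,1,58.0,31.0,10.9,16.0
Salcininkai,911,0,66,0,0,,48.3,0.15,3,50.8,0.0,25.8,25.0
Siauliai,1453,0,91,70,0,,34.9,0.4,3,61.2,0.0,30.7,30.5
Silale,1493,14.6,220,60,1,213.13,28.7,1.35,1,53.5,19.0,9.0,25.4
Silute,1888,72.5,342,60,1,151.41,42.1,1.6,1,85.5,61.4,13.1,11.0
Sirvintos,1188,0,137,70,0,,33.3,0.4,3,64.3,0.0,19.6,44.7
Svencionys,1714,0,77,100,0,,60.4,0.55,0,57.1,0.0,48.9,8.2
Taurage,905,44.9,142,0,0,125.02,38.7,0.35,3,42.3,0.0,20.5,21.8
Telsiai,1692,0,149,140,0,21,35.6,0.75,2,55.1,16.0,10.2,28.9
Trakai,1179,0,111,70,0,,49.9,0.3,3,58.9,0.0,32.2,26.8
Ukmerge,1438,0,137,60,0,,32.6,0.4,3,56.2,0.0,34.7,21.5
Utena,1207,0,66,300,0,,33.7,0.9,2,57.0,26.6,15.3,15.2
Varena,1395,0,66,70,0,,68.8,0.3,3,52.3,0.0,43.7,8.6
Vilkaviskis,1230,0,190,150,0,37.25,11,1.2,1,54.6,9.5,15.1,29.9
Vilnius,2216,0,111,70,0,,41.7,0.4,3,46.7,0.0,21.4,25.2
Zarasai,1262,0,89,70,0,19.25,37.6,0.5,3,72.6,0.0,39.6,32.9
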