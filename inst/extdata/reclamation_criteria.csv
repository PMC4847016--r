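"factor","kind","level","low","high","use","grade"
"slope","numeric","",0,5,"cultivated","1"
"slope","numeric","",0,5,"garden","1"
"slope","numeric","",0,5,"forest","1"
"slope","numeric","",0,5,"construction","1"
"slope","numeric","",5,10,"cultivated","2"
"slope","numeric","",5,10,"garden","2"
"slope","numeric","",5,10,"forest","2"
"slope","numeric","",5,10,"construction","2"
"slope","numeric","",10,15,"cultivated","3"
"slope","numeric","",10,15,"garden","2"
"slope","numeric","",10,15,"forest","2"
"slope","numeric","",10,15,"construction","3"
"slope","numeric","",15,Inf,"cultivated","N"
"slope","numeric","",15,Inf,"garden","3"
"slope","numeric","",15,Inf,"forest","3"
"slope","numeric","",15,Inf,"construction","N"
"surface","category","loam_sandy_loam",NA,NA,"cultivated","1"
"surface","category","loam_sandy_loam",NA,NA,"garden","1"
"surface","category","loam_sandy_loam",NA,NA,"forest","1"
"surface","category","loam_sandy_loam",NA,NA,"construction","1"
"surface","category","rock_soil_mixture",NA,NA,"cultivated","N"
"surface","category","rock_soil_mixture",NA,NA,"garden","2|3"
"surface","category","rock_soil_mixture",NA,NA,"forest","2|3"
"surface","category","rock_soil_mixture",NA,NA,"construction","2"
"surface","category","sand_gravel",NA,NA,"cultivated","N"
"surface","category","sand_gravel",NA,NA,"garden","3"
"surface","category","sand_gravel",NA,NA,"forest","3"
"surface","category","sand_gravel",NA,NA,"construction","3"
"som","numeric","",1,Inf,"cultivated","1|2"
"som","numeric","",1,Inf,"garden","1"
"som","numeric","",1,Inf,"forest","1"
"som","numeric","",1,Inf,"construction","1"
"som","numeric","",0.5,1,"cultivated","3"
"som","numeric","",0.5,1,"garden","2|3"
"som","numeric","",0.5,1,"forest","2|3"
"som","numeric","",0.5,1,"construction","2"
"som","numeric","",0,0.5,"cultivated","N"
"som","numeric","",0,0.5,"garden","3"
"som","numeric","",0,0.5,"forest","3"
"som","numeric","",0,0.5,"construction","3"
"thickness","numeric","",80,Inf,"cultivated","1"
"thickness","numeric","",80,Inf,"garden","1"
"thickness","numeric","",80,Inf,"forest","1"
"thickness","numeric","",80,Inf,"construction","1"
"thickness","numeric","",60,80,"cultivated","1|2"
"thickness","numeric","",60,80,"garden","2"
"thickness","numeric","",60,80,"forest","2"
"thickness","numeric","",60,80,"construction","2"
"thickness","numeric","",40,60,"cultivated","2|3"
"thickness","numeric","",40,60,"garden","2|3"
"thickness","numeric","",40,60,"forest","2|3"
"thickness","numeric","",40,60,"construction","3"
"thickness","numeric","",10,40,"cultivated","3|N"
"thickness","numeric","",10,40,"garden","3|N"
"thickness","numeric","",10,40,"forest","3|N"
"thickness","numeric","",10,40,"construction","3|N"
"thickness","numeric","",0,10,"cultivated","N"
"thickness","numeric","",0,10,"garden","N"
"thickness","numeric","",0,10,"forest","N"
"thickness","numeric","",0,10,"construction","N"
"irrigation","category","full",NA,NA,"cultivated","1"
"irrigation","category","full",NA,NA,"garden","1"
"irrigation","category","full",NA,NA,"forest","1"
"irrigation","category","full",NA,NA,"construction","1"
"irrigation","category","basic",NA,NA,"cultivated","2"
"irrigation","category","basic",NA,NA,"garden","2"
"irrigation","category","basic",NA,NA,"forest","2"
"irrigation","category","basic",NA,NA,"construction","2"
"irrigation","category","none",NA,NA,"cultivated","N"
"irrigation","category","none",NA,NA,"garden","3|N"
"irrigation","category","none",NA,NA,"forest","3|N"
"irrigation","category","none",NA,NA,"construction","N"
"road_dist","numeric","",0,2000,"cultivated","1"
"road_dist","numeric","",0,2000,"garden","1"
"road_dist","numeric","",0,2000,"forest","1"
"road_dist","numeric","",0,2000,"construction","1"
"road_dist","numeric","",2000,4000,"cultivated","2"
"road_dist","numeric","",2000,4000,"garden","2"
"road_dist","numeric","",2000,4000,"forest","2"
"road_dist","numeric","",2000,4000,"construction","2"
"road_dist","numeric","",4000,6000,"cultivated","3"
"road_dist","numeric","",4000,6000,"garden","3"
"road_dist","numeric","",4000,6000,"forest","3"
"road_dist","numeric","",4000,6000,"construction","3"
"road_dist","numeric","",6000,Inf,"cultivated","N"
"road_dist","numeric","",6000,Inf,"garden","3|N"
"road_dist","numeric","",6000,Inf,"forest","3|N"
"road_dist","numeric","",6000,Inf,"construction","N"
"damage","category","light",NA,NA,"cultivated","2"
"damage","category","light",NA,NA,"garden","2"
"damage","category","light",NA,NA,"forest","2"
"damage","category","light",NA,NA,"construction","1"
"damage","category","moderate",NA,NA,"cultivated","3"
"damage","category","moderate",NA,NA,"garden","3"
"damage","category","moderate",NA,NA,"forest","3"
"damage","category","moderate",NA,NA,"construction","2"
"damage","category","severe",NA,NA,"cultivated","N"
"damage","category","severe",NA,NA,"garden","3|N"
"damage","category","severe",NA,NA,"forest","3|N"
"damage","category","severe",NA,NA,"construction","3"
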