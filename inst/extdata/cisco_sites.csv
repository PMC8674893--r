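state,lake,site,latitude,longitude,max_depth_m,surface_area_km2,tdo3_max
Minnesota,Lower Hay,LHY,46.6693,-94.2843,42.06,57.75,22.5516
Minnesota,Sugar,SGR,45.3189,-94.0418,21.03,4.1,22.9099
Minnesota,Long,LNG,46.4895,-93.4938,35.36,1.76,17.4888
Wisconsin,Bear,BEA,45.6343,-91.8248,27,5.5,20.4916
Wisconsin,Grindstone,GRD,45.9353,-91.4154,18,12.6,22.7022
Wisconsin,Atkins,ATK,46.2789,-91.0367,24,0.7,12.5363
Wisconsin,Trude,TRU,46.1148,-90.1579,15,54.8,22.1987
Wisconsin,Pike,PIK,46.1747,-90.1196,25,0.8,11.4723
Wisconsin,Presque Isle,PRS,46.2227,-89.7798,24,5.2,17.84
Wisconsin,Trout,TRT,46.0303,-89.6766,36,15.4,11.4034
Wisconsin,White Sand,WSL,46.0887,-89.5941,2,3,12.1445
Wisconsin,Big Muskellunge,MSK,46.0174,-89.6149,21,3.8,16.1785
Wisconsin,Pallette,PLT,46.0665,-89.6039,20,0.7,15.2114
Wisconsin,Plum,PLM,46.0033,-89.5193,17,4.5,22.2666
Wisconsin,Tomahawk,TOM,45.8304,-89.6675,26,14.4,14.8864
Wisconsin,Two Sisters,TWS,45.7716,-89.5207,19,2.9,13.3695
Wisconsin,Black Oak,BLK,46.1612,-89.3155,26,2.4,9.4554
Wisconsin,Long,LGL,46.0645,-89.0225,29,3.5,12.5157
Wisconsin,Sevenmile,SVN,45.8811,-89.0506,13,2,22.3921
Wisconsin,Rainbow,RBW,44.3411,-89.1504,29,2.4,10.6171
Wisconsin,Spencer,SPN,44.2897,-89.1043,16,0.3,12.5953
Wisconsin,Gilbert,GIL,44.212,-89.1675,20,0.6,12.3836
Wisconsin,Green,GRN,43.8186,-88.9876,72,29.7,13.5789
Wisconsin,Elkhart,ELK,43.8262,-88.024,36,1.2,11.5196
Wisconsin,Okauchee,OKA,43.1262,-88.4232,29,4.8,20.5535
Wisconsin,Geneva,GNV,42.5637,-88.5179,41,21.3,11.2306
Michigan,Howard,HOW,42.0808,-85.5889,16.15,1.84,14.8317
Indiana,Eve,EVE,41.5603,-85.3199,12.8,0.3,17.4626
Indiana,Crooked,CRD,41.2634,-85.4803,32.9,1.6,13.2668
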