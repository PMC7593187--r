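region,n_region_label,Hn,Hu,Hd,pi,range_change_low_pct,range_change_high_pct
Vosges,Vosges,1,0,0,0,-100,-100
Scotland,Scotland,3,1,0.194,0.0003,-37.5,-25
Pyrenees,Pyrenees,5,3,0.629,0.004,-20,-73.3
Massif Central,Massif Central,2,1,0.545,0.0008,0,-50
England,England,7,6,0.638,0.0015,-50,-100
Carpathians,Carpathians,2,2,0.303,0.0005,-70.6,-100
Tatras,Tatras,2,2,0.409,0.0006,-25,-75
Cantabrians,Cantabrians,2,0,0.429,0.0059,-63.6,-81.8
Balkans West,Balkans West,4,3,0.423,0.0024,-75,-100
Apennines,Apennines,2,1,0.303,0.0005,-100,-100
Alps West,Alps (pooled),7,5,0.912,0.0043,-14.3,-41.3
Alps East,Alps (pooled),2,1,0.303,0.0005,-14.3,-41.3
Alps Central,Alps (pooled),2,1,0.182,0.0006,-14.3,-41.3
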