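construct,site,kind,Vd,Vd_sd,z,z_sd,n,gv_method
WT,WT,aa,-25.9,3.4,3.4,0.7,10,tail
L358Leu,L358,aa,-25.6,2.3,3.2,0.3,7,tail
L358Lah,L358,ah,-14.4,3.6,3.1,0.6,7,tail
I360Ile,I360,aa,-22.2,2.6,2.7,0.5,7,tail
I360Iah,I360,ah,-13.9,4.5,4.8,0.9,5,tail
L361Leu,L361,aa,-28.1,3.0,3.2,0.7,8,tail
L361Lah,L361,ah,1.3,3.7,3.0,0.4,13,tail
V363Val,V363,aa,-28.6,3.8,3.3,0.2,4,tail
V363Vah,V363,ah,-14.7,5.1,2.2,0.3,5,tail
I364Ile,I364,aa,-21.3,0.6,2.9,0.3,3,tail
I364Iah,I364,ah,-11.2,5.2,2.5,0.6,7,tail
L366Leu,L366,aa,-23.5,2.5,2.8,1.0,8,tail
L366Lah,L366,ah,-17.8,1.9,2.0,0.5,11,tail
V367Val,V367,aa,-24.0,4.1,3.1,0.7,7,tail
V367Vah,V367,ah,1.4,5.3,2.3,0.5,8,tail
V369Val,V369,aa,-25.5,6.0,3.8,0.6,9,chord
V369Vah,V369,ah,33.0,7.9,1.9,0.2,10,chord
F370Phe,F370,aa,-21.5,2.9,2.8,0.3,5,tail
F370Fah,F370,ah,13.6,2.0,2.9,0.2,7,tail
L375Leu,L375,aa,-26.0,2.6,3.5,0.6,8,tail
L375Lah,L375,ah,-23.4,3.8,3.8,0.6,14,tail
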