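symbol,atomic_number,period,group,metallicity,radius_pm,weight
H,1,1,1,nonmetal,31.0,1.008
He,2,1,18,nonmetal,28.0,4.003
Li,3,2,1,metal,128.0,6.941
Be,4,2,2,metal,96.0,9.012
B,5,2,13,metalloid,84.0,10.812
C,6,2,14,nonmetal,76.0,12.011
N,7,2,15,nonmetal,71.0,14.007
O,8,2,16,nonmetal,66.0,15.999
F,9,2,17,nonmetal,57.0,18.998
Ne,10,2,18,nonmetal,58.0,20.18
Na,11,3,1,metal,166.0,22.99
Mg,12,3,2,metal,141.0,24.305
Al,13,3,13,metal,121.0,26.982
Si,14,3,14,metalloid,111.0,28.086
P,15,3,15,nonmetal,107.0,30.974
S,16,3,16,nonmetal,105.0,32.067
Cl,17,3,17,nonmetal,102.0,35.453
Ar,18,3,18,nonmetal,106.0,39.948
K,19,4,1,metal,203.0,39.098
Ca,20,4,2,metal,176.0,40.078
Sc,21,4,3,metal,170.0,44.956
Ti,22,4,4,metal,160.0,47.867
V,23,4,5,metal,152.0,50.944
Cr,24,4,6,metal,139.0,51.996
Mn,25,4,7,metal,139.0,54.938
Fe,26,4,8,metal,132.0,55.845
Co,27,4,9,metal,126.0,58.933
Ni,28,4,10,metal,124.0,58.693
Cu,29,4,11,metal,132.0,63.546
Zn,30,4,12,metal,122.0,65.39
Ga,31,4,13,metal,122.0,69.723
Ge,32,4,14,metalloid,120.0,72.61
As,33,4,15,metalloid,119.0,74.922
Se,34,4,16,nonmetal,120.0,78.96
Br,35,4,17,nonmetal,120.0,79.904
Kr,36,4,18,nonmetal,116.0,83.8
Rb,37,5,1,metal,220.0,85.468
Sr,38,5,2,metal,195.0,87.62
Y,39,5,3,metal,190.0,88.906
Zr,40,5,4,metal,175.0,91.224
Nb,41,5,5,metal,164.0,92.906
Mo,42,5,6,metal,154.0,95.94
Tc,43,5,7,metal,147.0,98.0
Ru,44,5,8,metal,146.0,101.07
Rh,45,5,9,metal,142.0,102.906
Pd,46,5,10,metal,139.0,106.42
Ag,47,5,11,metal,145.0,107.868
Cd,48,5,12,metal,144.0,112.412
In,49,5,13,metal,142.0,114.818
Sn,50,5,14,metal,139.0,118.711
Sb,51,5,15,metalloid,139.0,121.76
Te,52,5,16,metalloid,138.0,127.6
I,53,5,17,nonmetal,139.0,126.904
Xe,54,5,18,nonmetal,140.0,131.29
Cs,55,6,1,metal,244.0,132.905
Ba,56,6,2,metal,215.0,137.328
La,57,6,3,metal,207.0,138.906
Ce,58,6,3,metal,204.0,140.116
Pr,59,6,3,metal,203.0,140.908
Nd,60,6,3,metal,201.0,144.24
Pm,61,6,3,metal,199.0,145.0
Sm,62,6,3,metal,198.0,150.36
Eu,63,6,3,metal,198.0,151.964
Gd,64,6,3,metal,196.0,157.25
Tb,65,6,3,metal,194.0,158.925
Dy,66,6,3,metal,192.0,162.5
Ho,67,6,3,metal,192.0,164.93
Er,68,6,3,metal,189.0,167.26
Tm,69,6,3,metal,190.0,168.934
Yb,70,6,3,metal,187.0,173.04
Lu,71,6,3,metal,187.0,174.967
Hf,72,6,4,metal,175.0,178.49
Ta,73,6,5,metal,170.0,180.948
W,74,6,6,metal,162.0,183.84
Re,75,6,7,metal,151.0,186.207
Os,76,6,8,metal,144.0,190.23
Ir,77,6,9,metal,141.0,192.217
Pt,78,6,10,metal,136.0,195.078
Au,79,6,11,metal,136.0,196.967
Hg,80,6,12,metal,132.0,200.59
Tl,81,6,13,metal,145.0,204.383
Pb,82,6,14,metal,146.0,207.2
Bi,83,6,15,metal,148.0,208.98
Po,84,6,16,metalloid,140.0,209.0
At,85,6,17,metalloid,150.0,210.0
Rn,86,6,18,nonmetal,150.0,222.0
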