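name,formula,conjugation_class,hydroxyl_class,parent_name,parent_formula,isomer_group,reference_rt_min,is_internal_standard,deuterium_count
CA,C24H40O5,unconjugated,tri,,,CA,19.8,FALSE,0
ACA,C24H40O5,unconjugated,tri,,,CA,21.0,FALSE,0
UCA,C24H40O5,unconjugated,tri,,,CA,12.8,FALSE,0
alpha-MCA,C24H40O5,unconjugated,tri,,,CA,15.4,FALSE,0
beta-MCA,C24H40O5,unconjugated,tri,,,CA,16.2,FALSE,0
omega-MCA,C24H40O5,unconjugated,tri,,,CA,13.4,FALSE,0
CDCA,C24H40O4,unconjugated,di,,,CDCA,28.7,FALSE,0
DCA,C24H40O4,unconjugated,di,,,CDCA,29.5,FALSE,0
HDCA,C24H40O4,unconjugated,di,,,CDCA,23.2,FALSE,0
UDCA,C24H40O4,unconjugated,di,,,CDCA,21.4,FALSE,0
IDCA,C24H40O4,unconjugated,di,,,CDCA,31.0,FALSE,0
muro-CA,C24H40O4,unconjugated,di,,,CDCA,20.6,FALSE,0
LCA,C24H40O3,unconjugated,mono,,,LCA,38.5,FALSE,0
ILCA,C24H40O3,unconjugated,mono,,,LCA,40.0,FALSE,0
AILCA,C24H40O3,unconjugated,mono,,,LCA,41.0,FALSE,0
12-keto-DCA,C24H38O5,unconjugated,other,,,keto-DCA,14.2,FALSE,0
7-keto-DCA,C24H38O5,unconjugated,other,,,keto-DCA,13.2,FALSE,0
3-DHCA,C24H38O5,unconjugated,other,,,keto-DCA,12.4,FALSE,0
12-keto-LCA,C24H38O4,unconjugated,other,,,keto-LCA,24.6,FALSE,0
7-keto-LCA,C24H38O4,unconjugated,other,,,keto-LCA,21.9,FALSE,0
APCA,C24H38O4,unconjugated,other,,,keto-LCA,28.0,FALSE,0
DHLCA,C24H38O3,unconjugated,other,,,DHLCA,35.5,FALSE,0
DHCA,C24H34O5,unconjugated,other,,,DHCA,8.8,FALSE,0
di-oxo-LCA,C24H36O5,unconjugated,other,,,di-oxo-LCA,17.0,FALSE,0
"6,7-diketo-LCA",C24H36O5,unconjugated,other,,,di-oxo-LCA,18.0,FALSE,0
NCA,C23H38O5,unconjugated,other,,,NCA,11.5,FALSE,0
NDCA,C23H38O4,unconjugated,other,,,NDCA,16.8,FALSE,0
NUDCA,C23H38O4,unconjugated,other,,,NDCA,14.0,FALSE,0
GCA,C26H43NO6,glycine,tri,CA,C24H40O5,GCA,12.6,FALSE,0
GHCA,C26H43NO6,glycine,tri,HCA,C24H40O5,GCA,7.6,FALSE,0
GCDCA,C26H43NO5,glycine,di,CDCA,C24H40O4,GCDCA,16.5,FALSE,0
GDCA,C26H43NO5,glycine,di,DCA,C24H40O4,GCDCA,17.4,FALSE,0
GHDCA,C26H43NO5,glycine,di,HDCA,C24H40O4,GCDCA,14.8,FALSE,0
GUDCA,C26H43NO5,glycine,di,UDCA,C24H40O4,GCDCA,12.2,FALSE,0
GLCA,C26H43NO4,glycine,mono,LCA,C24H40O3,GLCA,24.0,FALSE,0
GDHCA,C26H37NO6,glycine,other,DHCA,C24H34O5,GDHCA,5.0,FALSE,0
TCA,C26H45NO7S,taurine,tri,CA,C24H40O5,TCA,7.2,FALSE,0
THCA,C26H45NO7S,taurine,tri,HCA,C24H40O5,TCA,6.6,FALSE,0
alpha-TMCA,C26H45NO7S,taurine,tri,alpha-MCA,C24H40O5,TCA,4.8,FALSE,0
beta-TMCA,C26H45NO7S,taurine,tri,beta-MCA,C24H40O5,TCA,5.4,FALSE,0
omega-TMCA,C26H45NO7S,taurine,tri,omega-MCA,C24H40O5,TCA,6.0,FALSE,0
TCDCA,C26H45NO6S,taurine,di,CDCA,C24H40O4,TCDCA,9.0,FALSE,0
TDCA,C26H45NO6S,taurine,di,DCA,C24H40O4,TCDCA,9.6,FALSE,0
TUDCA,C26H45NO6S,taurine,di,UDCA,C24H40O4,TCDCA,8.0,FALSE,0
TLCA,C26H45NO5S,taurine,mono,LCA,C24H40O3,TLCA,13.0,FALSE,0
TDHCA,C26H39NO7S,taurine,other,DHCA,C24H34O5,TDHCA,4.0,FALSE,0
d4-GUDCA,C26H43NO5,glycine,di,UDCA,C24H40O4,,12.18,TRUE,4
d4-GCA,C26H43NO6,glycine,tri,CA,C24H40O5,,12.58,TRUE,4
d4-TUDCA,C26H45NO6S,taurine,di,UDCA,C24H40O4,,7.98,TRUE,4
d4-TCA,C26H45NO7S,taurine,tri,CA,C24H40O5,,7.18,TRUE,4
d4-CA,C24H40O5,unconjugated,tri,,,,19.78,TRUE,4
d4-UDCA,C24H40O4,unconjugated,di,,,,21.38,TRUE,4
d4-GCDCA,C26H43NO5,glycine,di,CDCA,C24H40O4,,16.48,TRUE,4
d4-GDCA,C26H43NO5,glycine,di,DCA,C24H40O4,,17.38,TRUE,4
d4-TCDCA,C26H45NO6S,taurine,di,CDCA,C24H40O4,,8.98,TRUE,4
d6-TDCA,C26H45NO6S,taurine,di,DCA,C24H40O4,,9.58,TRUE,6
d4-CDCA,C24H40O4,unconjugated,di,,,,28.68,TRUE,4
d4-DCA,C24H40O4,unconjugated,di,,,,29.48,TRUE,4
d4-GLCA,C26H43NO4,glycine,mono,LCA,C24H40O3,,23.98,TRUE,4
d4-LCA,C24H40O3,unconjugated,mono,,,,38.48,TRUE,4
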