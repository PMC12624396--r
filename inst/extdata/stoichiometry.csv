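metabolite,carbon_atoms,phosphate_groups,pools,excluded_from_CCM
3PGA,3,1,CBC;energy_shuttle,FALSE
DHAP,3,1,CBC;energy_shuttle,FALSE
FBP,6,2,CBC;CBC_minus_shuttle,FALSE
F6P,6,1,CBC;CBC_minus_shuttle,FALSE
SBP,7,2,CBC;CBC_minus_shuttle,FALSE
S7P,7,1,CBC;CBC_minus_shuttle,FALSE
R5P,5,1,CBC;CBC_minus_shuttle,FALSE
Ru5P+Xu5P,5,1,CBC;CBC_minus_shuttle,FALSE
RuBP,5,2,CBC;CBC_minus_shuttle,FALSE
PEP,3,1,CCM,FALSE
pyruvate,3,0,CCM,FALSE
alanine,3,0,CCM,FALSE
aspartate,4,0,CCM,FALSE
malate,4,0,,TRUE
2PG,2,1,photorespiration,FALSE
glycolate,2,0,photorespiration,FALSE
glycine,2,0,photorespiration,FALSE
serine,3,0,photorespiration,FALSE
glycerate,3,0,photorespiration,FALSE
ADPG,6,2,end_product,FALSE
UDPG,6,2,end_product,FALSE
G6P,6,1,end_product,FALSE
G1P,6,1,end_product,FALSE
sucrose,12,0,end_product,FALSE
glucose,6,0,end_product,FALSE
fructose,6,0,end_product,FALSE
raffinose,18,0,end_product,FALSE
maltose,12,0,end_product,FALSE
glutamate,5,0,,FALSE
glutamine,5,0,,FALSE
2OG,5,0,,FALSE
fumarate,4,0,,FALSE
citrate,6,0,,FALSE
isocitrate,6,0,,FALSE
succinate,4,0,,FALSE
shikimate,7,0,,FALSE
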