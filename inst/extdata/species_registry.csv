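name,kind,charge,hofmeister_rank,peg_mass
ammonium,cation,1,1,NA
cesium,cation,1,2,NA
rubidium,cation,1,3,NA
potassium,cation,1,4,NA
lithium,cation,1,5,NA
sodium,cation,1,6,NA
barium,cation,2,7,NA
magnesium,cation,2,8,NA
manganese,cation,2,9,NA
zinc,cation,2,10,NA
cadmium,cation,2,11,NA
calcium,cation,2,12,NA
cobalt,cation,2,13,NA
copper,cation,2,14,NA
nickel,cation,2,15,NA
strontium,cation,2,16,NA
iron,cation,3,17,NA
gadolinium,cation,3,18,NA
samarium,cation,3,19,NA
phosphate_tribasic,anion,-3,1,NA
citrate_tribasic,anion,-3,2,NA
sulfate,anion,-2,3,NA
tartrate,anion,-2,4,NA
carbonate,anion,-2,5,NA
thiosulfate,anion,-2,6,NA
phosphate_dibasic,anion,-2,7,NA
succinate,anion,-2,8,NA
citrate,anion,-1,9,NA
acetate,anion,-1,10,NA
malonate,anion,-2,11,NA
fluoride,anion,-1,12,NA
formate,anion,-1,13,NA
chloride,anion,-1,14,NA
bromide,anion,-1,15,NA
iodide,anion,-1,16,NA
phosphate_monobasic,anion,-1,17,NA
thiocyanate,anion,-1,18,NA
cacodylate,anion,-1,NA,NA
molybdate,anion,-2,NA,NA
nitrate,anion,-1,NA,NA
pyrophosphate_tetrabasic,anion,-4,NA,NA
tetraborate,anion,-2,NA,NA
aminosalicylate_4,anion,-1,NA,NA
peg_200,PEG,0,NA,200
peg_400,PEG,0,NA,400
peg_550,PEG,0,NA,550
peg_1000,PEG,0,NA,1000
peg_1500,PEG,0,NA,1500
peg_2000,PEG,0,NA,2000
peg_3350,PEG,0,NA,3350
peg_4000,PEG,0,NA,4000
peg_5000,PEG,0,NA,5000
peg_6000,PEG,0,NA,6000
peg_8000,PEG,0,NA,8000
peg_10000,PEG,0,NA,10000
peg_20000,PEG,0,NA,20000
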