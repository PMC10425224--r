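# cottonwl packaged response-curve registry, version "published compilation, as printed 2023"
# Coefficients a, b, c are stored exactly as printed; linear rows are stored in
# printed column order and re-oriented to (slope, intercept) by the loader's
# nearest-to-1-intercept rule. Families: linear y = slope*x + intercept,
# quadratic y = a*x^2 + b*x + c, exp_decay y = a*exp(b*x); x = days waterlogged.
parameter_code,description,family,a,b,c,r_squared
PH,Plant height,quadratic,0.0032,-0.087,1.056,0.96
SD,Stem diameter,quadratic,0.0039,-0.098,1.101,0.98
LN,Mainstem leaf number,quadratic,0.0017,-0.054,1.023,0.97
LA,Leaf area,exp_decay,0.9770,-0.158,,0.92
DWL,Dry weight of leaves,exp_decay,0.9188,-0.118,,0.85
DWS,Dry weight of stems,exp_decay,0.9157,-0.118,,0.84
DWSh,Dry weight of shoot,exp_decay,0.9410,-0.121,,0.87
DWT,Dry weight of whole plant,exp_decay,0.9611,-0.123,,0.88
RL,Root length,linear,-0.0696,1.078,,0.94
RSA,Root surface area,linear,-0.0698,1.087,,0.93
RV,Root volume,linear,-0.0699,1.096,,0.94
RWD,Root dry weight,quadratic,0.0038,-0.122,1.1,0.95
RT,Root tips,quadratic,0.0028,-0.093,1.128,0.86
RC,Root crossings,quadratic,0.002,-0.107,1.059,0.98
CHL,Chlorophyll,linear,0.98,0.0055,,0.75
FL,Flavonoid index,linear,0.80,0.015,,0.41
AN,Anthocyanin,linear,0.79,0.012,,0.57
NBI,Nitrogen balance index,linear,0.98,0.020,,0.74
P,Leaf photosynthesis,linear,1.2,-0.051,,0.59
E,Transpiration,linear,1.4,-0.065,,0.58
CiCa,Ratio of intercellular and ambient CO2 concentrations,linear,1.1,-0.021,,0.51
Gs,Stomatal conductance,linear,1.4,-0.069,,0.59
ETR,Photosynthetic electron transport rate,linear,1.1,-0.028,,0.72
PhiPS2,PSII actual photochemical quantum yield,linear,1.2,-0.049,,0.71
NPQ,Nonphotochemical chlorophyll fluorescence quenching,linear,0.051,0.052,,0.77
FvFm,PSII effective chlorophyll fluorescence,linear,1.1,-0.013,,0.80
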