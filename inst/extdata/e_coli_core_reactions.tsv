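reaction	reversible	lb	ub	objective	subsystem
ACALD	1	-1000.0	1000.0	0.0	Pyruvate Metabolism
ACALDt	1	-1000.0	1000.0	0.0	Transport, Extracellular
ACKr	1	-1000.0	1000.0	0.0	Pyruvate Metabolism
ACONTa	1	-1000.0	1000.0	0.0	Citric Acid Cycle
ACONTb	1	-1000.0	1000.0	0.0	Citric Acid Cycle
ACt2r	1	-1000.0	1000.0	0.0	Transport, Extracellular
ADK1	1	-1000.0	1000.0	0.0	Oxidative Phosphorylation
AKGDH	0	0.0	1000.0	0.0	Citric Acid Cycle
AKGt2r	1	-1000.0	1000.0	0.0	Transport, Extracellular
ALCD2x	1	-1000.0	1000.0	0.0	Pyruvate Metabolism
ATPM	0	8.39	1000.0	0.0	Oxidative Phosphorylation
ATPS4r	1	-1000.0	1000.0	0.0	Oxidative Phosphorylation
Biomass_Ecoli_core	0	0.0	1000.0	1.0	Biomass and Maintenance Functions
CO2t	1	-1000.0	1000.0	0.0	Transport, Extracellular
CS	0	0.0	1000.0	0.0	Citric Acid Cycle
CYTBD	0	0.0	1000.0	0.0	Oxidative Phosphorylation
D_LACt2	1	-1000.0	1000.0	0.0	Transport, Extracellular
ENO	1	-1000.0	1000.0	0.0	Glycolysis/Gluconeogenesis
ETOHt2r	1	-1000.0	1000.0	0.0	Transport, Extracellular
EX_ac_e	1	0.0	1000.0	0.0	Exchange
EX_acald_e	1	0.0	1000.0	0.0	Exchange
EX_akg_e	1	0.0	1000.0	0.0	Exchange
EX_co2_e	1	-1000.0	1000.0	0.0	Exchange
EX_etoh_e	1	0.0	1000.0	0.0	Exchange
EX_for_e	1	0.0	1000.0	0.0	Exchange
EX_fru_e	1	0.0	1000.0	0.0	Exchange
EX_fum_e	1	0.0	1000.0	0.0	Exchange
EX_glc__D_e	1	-10.0	1000.0	0.0	Exchange
EX_gln__L_e	1	0.0	1000.0	0.0	Exchange
EX_glu__L_e	1	0.0	1000.0	0.0	Exchange
EX_h_e	1	-1000.0	1000.0	0.0	Exchange
EX_h2o_e	1	-1000.0	1000.0	0.0	Exchange
EX_lac__D_e	1	0.0	1000.0	0.0	Exchange
EX_mal__L_e	1	0.0	1000.0	0.0	Exchange
EX_nh4_e	1	-1000.0	1000.0	0.0	Exchange
EX_o2_e	1	-1000.0	1000.0	0.0	Exchange
EX_pi_e	1	-1000.0	1000.0	0.0	Exchange
EX_pyr_e	1	0.0	1000.0	0.0	Exchange
EX_succ_e	1	0.0	1000.0	0.0	Exchange
FBA	1	-1000.0	1000.0	0.0	Glycolysis/Gluconeogenesis
FBP	0	0.0	1000.0	0.0	Glycolysis/Gluconeogenesis
FORt2	0	0.0	1000.0	0.0	Transport, Extracellular
FORti	0	0.0	1000.0	0.0	Transport, Extracellular
FRD7	0	0.0	1000.0	0.0	Oxidative Phosphorylation
FRUpts2	0	0.0	1000.0	0.0	Transport, Extracellular
FUM	1	-1000.0	1000.0	0.0	Citric Acid Cycle
FUMt2_2	0	0.0	1000.0	0.0	Transport, Extracellular
G6PDH2r	1	-1000.0	1000.0	0.0	Pentose Phosphate Pathway
GAPD	1	-1000.0	1000.0	0.0	Glycolysis/Gluconeogenesis
GLCpts	0	0.0	1000.0	0.0	Glycolysis/Gluconeogenesis
GLNS	0	0.0	1000.0	0.0	Glutamate Metabolism
GLNabc	0	0.0	1000.0	0.0	Transport, Extracellular
GLUDy	1	-1000.0	1000.0	0.0	Glutamate Metabolism
GLUN	0	0.0	1000.0	0.0	Glutamate Metabolism
GLUSy	0	0.0	1000.0	0.0	Glutamate Metabolism
GLUt2r	1	-1000.0	1000.0	0.0	Transport, Extracellular
GND	0	0.0	1000.0	0.0	Pentose Phosphate Pathway
H2Ot	1	-1000.0	1000.0	0.0	Transport, Extracellular
ICDHyr	1	-1000.0	1000.0	0.0	Citric Acid Cycle
ICL	0	0.0	1000.0	0.0	Anaplerotic Reactions
LDH_D	1	-1000.0	1000.0	0.0	Pyruvate Metabolism
MALS	0	0.0	1000.0	0.0	Anaplerotic Reactions
MALt2_2	0	0.0	1000.0	0.0	Transport, Extracellular
MDH	1	-1000.0	1000.0	0.0	Citric Acid Cycle
ME1	0	0.0	1000.0	0.0	Anaplerotic Reactions
ME2	0	0.0	1000.0	0.0	Anaplerotic Reactions
NADH16	0	0.0	1000.0	0.0	Oxidative Phosphorylation
NADTRHD	0	0.0	1000.0	0.0	Oxidative Phosphorylation
NH4t	1	-1000.0	1000.0	0.0	Inorganic Ion Transport and Metabolism
O2t	1	-1000.0	1000.0	0.0	Transport, Extracellular
PDH	0	0.0	1000.0	0.0	Glycolysis/Gluconeogenesis
PFK	0	0.0	1000.0	0.0	Glycolysis/Gluconeogenesis
PFL	0	0.0	1000.0	0.0	Pyruvate Metabolism
PGI	1	-1000.0	1000.0	0.0	Glycolysis/Gluconeogenesis
PGK	1	-1000.0	1000.0	0.0	Glycolysis/Gluconeogenesis
PGL	0	0.0	1000.0	0.0	Pentose Phosphate Pathway
PGM	1	-1000.0	1000.0	0.0	Glycolysis/Gluconeogenesis
PIt2r	1	-1000.0	1000.0	0.0	Inorganic Ion Transport and Metabolism
PPC	0	0.0	1000.0	0.0	Anaplerotic Reactions
PPCK	0	0.0	1000.0	0.0	Anaplerotic Reactions
PPS	0	0.0	1000.0	0.0	Glycolysis/Gluconeogenesis
PTAr	1	-1000.0	1000.0	0.0	Pyruvate Metabolism
PYK	0	0.0	1000.0	0.0	Glycolysis/Gluconeogenesis
PYRt2	1	-1000.0	1000.0	0.0	Transport, Extracellular
RPE	1	-1000.0	1000.0	0.0	Pentose Phosphate Pathway
RPI	1	-1000.0	1000.0	0.0	Pentose Phosphate Pathway
SUCCt2_2	0	0.0	1000.0	0.0	Transport, Extracellular
SUCCt3	0	0.0	1000.0	0.0	Transport, Extracellular
SUCDi	0	0.0	1000.0	0.0	Oxidative Phosphorylation
SUCOAS	1	-1000.0	1000.0	0.0	Citric Acid Cycle
TALA	1	-1000.0	1000.0	0.0	Pentose Phosphate Pathway
THD2	0	0.0	1000.0	0.0	Oxidative Phosphorylation
TKT1	1	-1000.0	1000.0	0.0	Pentose Phosphate Pathway
TKT2	1	-1000.0	1000.0	0.0	Pentose Phosphate Pathway
TPI	1	-1000.0	1000.0	0.0	Glycolysis/Gluconeogenesis
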