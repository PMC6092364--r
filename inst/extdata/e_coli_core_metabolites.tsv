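metabolite	compartment
13dpg_c	c
2pg_c	c
3pg_c	c
6pgc_c	c
6pgl_c	c
ac_c	c
ac_e	e
acald_c	c
acald_e	e
accoa_c	c
acon_C_c	c
actp_c	c
adp_c	c
akg_c	c
akg_e	e
amp_c	c
atp_c	c
cit_c	c
co2_c	c
co2_e	e
coa_c	c
dhap_c	c
e4p_c	c
etoh_c	c
etoh_e	e
f6p_c	c
fdp_c	c
for_c	c
for_e	e
fru_e	e
fum_c	c
fum_e	e
g3p_c	c
g6p_c	c
glc__D_e	e
gln__L_c	c
gln__L_e	e
glu__L_c	c
glu__L_e	e
glx_c	c
h2o_c	c
h2o_e	e
h_c	c
h_e	e
icit_c	c
lac__D_c	c
lac__D_e	e
mal__L_c	c
mal__L_e	e
nad_c	c
nadh_c	c
nadp_c	c
nadph_c	c
nh4_c	c
nh4_e	e
o2_c	c
o2_e	e
oaa_c	c
pep_c	c
pi_c	c
pi_e	e
pyr_c	c
pyr_e	e
q8_c	c
q8h2_c	c
r5p_c	c
ru5p__D_c	c
s7p_c	c
succ_c	c
succ_e	e
succoa_c	c
xu5p__D_c	c
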