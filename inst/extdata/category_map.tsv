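gene	category
CHEK2	DNA_REPAIR_CELL_CYCLE
POLL	DNA_REPAIR_CELL_CYCLE
RECQL	DNA_REPAIR_CELL_CYCLE
SHCBP1	DNA_REPAIR_CELL_CYCLE
PRC1	DNA_REPAIR_CELL_CYCLE
CDK18	DNA_REPAIR_CELL_CYCLE
RRM2	DNA_REPAIR_CELL_CYCLE
FAAP24	DNA_REPAIR_CELL_CYCLE
SMC2	DNA_REPAIR_CELL_CYCLE
FANCI	DNA_REPAIR_CELL_CYCLE
MCPH1	DNA_REPAIR_CELL_CYCLE
ENDOV	DNA_REPAIR_CELL_CYCLE
ZW10	DNA_REPAIR_CELL_CYCLE
EXO1	DNA_REPAIR_CELL_CYCLE
RECQL5	DNA_REPAIR_CELL_CYCLE
XRCC1	DNA_REPAIR_CELL_CYCLE
LAMC2	ECM_FOCAL_ADHESION
COL12A1	ECM_FOCAL_ADHESION
COL4A4	ECM_FOCAL_ADHESION
ADAMTS14	ECM_FOCAL_ADHESION
COL1A2	ECM_FOCAL_ADHESION
ITGB4	ECM_FOCAL_ADHESION
COL6A3	ECM_FOCAL_ADHESION
FLNC	ECM_FOCAL_ADHESION
ITGA10	ECM_FOCAL_ADHESION
COL11A1	ECM_FOCAL_ADHESION
SMAD4	TGFB_SIGNALING
SMAD6	TGFB_SIGNALING
ACVR1C	TGFB_SIGNALING
DMBT1	OTHER
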