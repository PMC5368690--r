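gene	breast
GENE00001	TRUE
GENE00003	FALSE
GENE00005	TRUE
GENE00017	FALSE
GENE00020	TRUE
GENE00030	FALSE
GENE00031	FALSE
GENE00032	FALSE
GENE00033	FALSE
GENE00034	FALSE
GENE00035	FALSE
GENE00036	FALSE
GENE00037	FALSE
GENE00038	FALSE
GENE00039	FALSE
GENE00040	FALSE
GENE00041	FALSE
GENE00042	FALSE
GENE00043	FALSE
GENE00044	FALSE
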