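# Editable keyword -> function mapping applied to _struct_keywords.pdbx_keywords.
# Matching is case-insensitive on the full keyword string; unmapped keywords
# pass through as NA so they remain visible in exports.
keyword	fun
OXIDOREDUCTASE	Oxidoreductase
OXIDOREDUCTASE (OXYGENASE)	Oxidoreductase
OXIDOREDUCTASE (PEROXIDASE)	Oxidoreductase
OXIDOREDUCTASE (H2O2(A))	Oxidoreductase
ELECTRON TRANSPORT	Electron transport
ELECTRON TRANSFER	Electron transport
ELECTRON TRANSPORT (HEME PROTEIN)	Electron transport
OXYGEN STORAGE	Oxygen binding
OXYGEN TRANSPORT	Oxygen binding
OXYGEN STORAGE/TRANSPORT	Oxygen binding
OXYGEN BINDING	Oxygen binding
TRANSPORT PROTEIN	Transport
METAL TRANSPORT	Transport
SIGNALING PROTEIN	Signaling
HYDROLASE	Hydrolase
LYASE	Lyase
ISOMERASE	Isomerase
LIGASE	Ligase
TRANSFERASE	Transferase
HEME-BINDING PROTEIN	Heme binding
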