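# Default CAZyme family -> substrate class map (see default_activity_map()).
# Cellulases: endo-/exo-glucanases and processive cellulases named in the
# cellulosome literature (GH5, GH7, GH9, GH12, GH48, ...); hemicellulases:
# xylanases/mannanases/arabinofuranosidases (GH10, GH11, GH26, GH43, ...);
# oligosaccharide-active: beta-glucosidases/-galactosidases and relatives.
# Unlisted families resolve to OTHER. Edit and load with read_activity_map().
family	class
GH5	CELLULOSE
GH6	CELLULOSE
GH7	CELLULOSE
GH8	CELLULOSE
GH9	CELLULOSE
GH12	CELLULOSE
GH44	CELLULOSE
GH45	CELLULOSE
GH48	CELLULOSE
GH124	CELLULOSE
GH10	HEMICELLULOSE
GH11	HEMICELLULOSE
GH26	HEMICELLULOSE
GH30	HEMICELLULOSE
GH43	HEMICELLULOSE
GH51	HEMICELLULOSE
GH53	HEMICELLULOSE
GH54	HEMICELLULOSE
GH62	HEMICELLULOSE
GH67	HEMICELLULOSE
GH74	HEMICELLULOSE
GH115	HEMICELLULOSE
GH1	OLIGOSACCHARIDE
GH2	OLIGOSACCHARIDE
GH3	OLIGOSACCHARIDE
GH20	OLIGOSACCHARIDE
GH29	OLIGOSACCHARIDE
GH31	OLIGOSACCHARIDE
GH35	OLIGOSACCHARIDE
GH36	OLIGOSACCHARIDE
GH38	OLIGOSACCHARIDE
GH39	OLIGOSACCHARIDE
GH42	OLIGOSACCHARIDE
GH94	OLIGOSACCHARIDE
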