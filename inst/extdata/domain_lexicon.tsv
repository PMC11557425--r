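# Default domain lexicon: member-database accession -> canonical label.
# Mirrors default_lexicon(); edit/extend and load with read_lexicon().
# Typed cohesin/dockerin CDD profiles follow the identifiers used in the
# cellulosome literature. Note on cd14255: it is listed here with the
# dockerin profiles (DOC3), but it has also been referred to as a Coh3
# profile; remap it if your annotation source treats it that way.
# GH-family assignments for the Pfam glycoside hydrolase profiles reflect
# the package authors' reading of the Pfam family descriptions.
accession	label
cd08548	COH1
cd08547	COH2
cd08759	COH3
PF00963	COH_GENERIC
cd14256	DOC1
cd14254	DOC2
cd14255	DOC3
PF00404	DOC_GENERIC
PF00942	CBM3
SSF49384	CBM_CELLULOSE_OTHER
PF00395	SLH
PF00746	LPXTG
PF01476	LYSM
TRANSMEMBRANE	TM_HELIX_CTERM
PF01179	CU_AMINE_OXIDASE
PF03442	X2
PF00041	FN3
SIGNAL_PEPTIDE	SIGNAL_PEPTIDE
RSGI_PROFILE	RSGI
G3DSA:2.60.40.680	COH_LIKE_FOLD
PF00150	GH5
PF00759	GH9
PF02011	GH48
PF01270	GH11
PF02015	GH45
PF01670	GH12
PF12891	GH44
PF03537	GH26
PF00331	GH10
PF04616	GH43
PF00232	GH1
PF00933	GH3
PF01341	GH6
PF00840	GH7
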