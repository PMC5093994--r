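# Default signature -> canonical motif map.
# Columns: signature <TAB> motif <TAB> sources
#   signature: accession after stripping any ".<n>" version suffix;
#              matched case-insensitively.
#   sources:   comma-separated evidence sources the row applies to, or "*".
# Accessions are the standard Pfam/SMART/Gene3D/Superfamily family models for
# each motif; edit or extend this file (or pass your own to
# load_signature_map) without touching code.
PF00931	NB-ARC	*
PF01582	TIR	*
PF13676	TIR	*
PF01476	LysM	*
SM00257	LysM	*
PF00069	KINASE	*
PF07714	KINASE	*
SM00220	KINASE	*
PF00560	LRR	*
PF07723	LRR	*
PF07725	LRR	*
PF12799	LRR	*
PF13306	LRR	*
PF13504	LRR	*
PF13516	LRR	*
PF13855	LRR	*
SM00369	LRR	*
G3DSA:3.80.10.10	LRR	Gene3D
3.80.10.10	LRR	Gene3D
SSF52058	LRR	Superfamily
SSF52047	LRR	Superfamily
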