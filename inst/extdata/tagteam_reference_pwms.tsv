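# Reference TAGteam position weight matrices (synthetic,
# consensus-derived). Built from the published Drosophila TAGteam
# consensus heptamers CAGGTAG, CAGGCAG and TAGGTAG by placing weight 0.91
# on the consensus base and 0.03 on each alternative at every position.
# These stand in for the original experimentally derived matrices, which
# are not redistributable here; substitute real matrices for production
# comparisons.
motif	base	pos1	pos2	pos3	pos4	pos5	pos6	pos7
CAGGTAG	A	0.03	0.91	0.03	0.03	0.03	0.91	0.03
CAGGTAG	C	0.91	0.03	0.03	0.03	0.03	0.03	0.03
CAGGTAG	G	0.03	0.03	0.91	0.91	0.03	0.03	0.91
CAGGTAG	T	0.03	0.03	0.03	0.03	0.91	0.03	0.03
CAGGCAG	A	0.03	0.91	0.03	0.03	0.03	0.91	0.03
CAGGCAG	C	0.91	0.03	0.03	0.03	0.91	0.03	0.03
CAGGCAG	G	0.03	0.03	0.91	0.91	0.03	0.03	0.91
CAGGCAG	T	0.03	0.03	0.03	0.03	0.03	0.03	0.03
TAGGTAG	A	0.03	0.91	0.03	0.03	0.03	0.91	0.03
TAGGTAG	C	0.03	0.03	0.03	0.03	0.03	0.03	0.03
TAGGTAG	G	0.03	0.03	0.91	0.91	0.03	0.03	0.91
TAGGTAG	T	0.91	0.03	0.03	0.03	0.91	0.03	0.03
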