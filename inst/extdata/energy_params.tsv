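# Nearest-neighbor duplex energy parameters (kcal/mol, 37 C).
# Stack keys read "<pair1>.<pair2>": two adjacent base pairs of an RNA
# duplex, each pair written as <miRNA base><target base>, stepping 5'->3'
# along the miRNA strand. Watson-Crick/Watson-Crick stack values are the
# standard Turner 2004 nearest-neighbor helix dG37 set (symmetry-expanded
# to all 16 ordered combinations). Stacks involving a G:U wobble pair are
# simplified to a uniform -1.0; replace with a full wobble table if higher
# fidelity is needed. Bulge and internal-loop penalties are simple linear
# costs in the number of unpaired bases. No duplex-initiation term.
type	key	value
stack	AU.AU	-0.93
stack	UA.UA	-0.93
stack	AU.UA	-1.10
stack	UA.AU	-1.33
stack	CG.UA	-2.08
stack	AU.GC	-2.08
stack	CG.AU	-2.11
stack	UA.GC	-2.11
stack	GC.UA	-2.24
stack	AU.CG	-2.24
stack	GC.AU	-2.35
stack	UA.CG	-2.35
stack	CG.GC	-2.36
stack	GC.GC	-3.26
stack	CG.CG	-3.26
stack	GC.CG	-3.42
stack	GU.AU	-1.0
stack	GU.UA	-1.0
stack	GU.GC	-1.0
stack	GU.CG	-1.0
stack	GU.GU	-1.0
stack	GU.UG	-1.0
stack	UG.AU	-1.0
stack	UG.UA	-1.0
stack	UG.GC	-1.0
stack	UG.CG	-1.0
stack	UG.GU	-1.0
stack	UG.UG	-1.0
stack	AU.GU	-1.0
stack	AU.UG	-1.0
stack	UA.GU	-1.0
stack	UA.UG	-1.0
stack	GC.GU	-1.0
stack	GC.UG	-1.0
stack	CG.GU	-1.0
stack	CG.UG	-1.0
scalar	bulge_init	3.0
scalar	bulge_per_nt	0.6
scalar	loop_init	3.5
scalar	loop_per_nt	0.4
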