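# Nearest-neighbor free energy parameters (dG at 37 C, kcal/mol).
# A documented Turner-2004-style subset: Watson-Crick helix stacks are the
# exact Xia/Turner dG37 values; G.U stacks are stated to ~0.1 kcal/mol;
# hairpin initiations for loops 3-9 are tabulated, longer loops are
# extrapolated as dG(L) = dG(9) + 1.75*R*T*ln(L/9) (Jacobson-Stockmayer),
# and likewise beyond the table ends of the bulge/internal tables.
# Single-nucleotide bulges keep the flanking helix stack and carry no
# terminal AU penalty; larger bulges and internal loops charge the terminal
# AU/GU penalty on both closing pairs.  Multiloops use an affine model
# (closing + per-branch + per-unpaired).  No tetraloop bonuses, terminal
# mismatches, dangling ends or coaxial stacking.
#
# stack lines: outer-pair inner-pair dG, where the outer pair is (i,j) and
# the inner pair is (i+1, j-1); the table is symmetric under helix flip,
# E(p,q) = E(rev q, rev p), and is stored in full.
name turner2004-subset
pairs AU UA CG GC GU UG
terminal_au 0.50
ml_closing 3.40
ml_branch 0.40
ml_unpaired 0.00
asym_coef 0.60
asym_max 3.00
min_hairpin 3
max_internal 30
stack AU AU -0.93
stack AU UA -1.10
stack AU CG -2.24
stack AU GC -2.08
stack AU GU -0.55
stack AU UG -1.40
stack UA AU -1.33
stack UA UA -0.93
stack UA CG -2.35
stack UA GC -2.11
stack UA GU -1.00
stack UA UG -1.30
stack CG AU -2.11
stack CG UA -2.08
stack CG CG -3.26
stack CG GC -2.36
stack CG GU -1.41
stack CG UG -2.11
stack GC AU -2.35
stack GC UA -2.24
stack GC CG -3.42
stack GC GC -3.26
stack GC GU -1.53
stack GC UG -2.51
stack GU AU -1.30
stack GU UA -1.40
stack GU CG -2.51
stack GU GC -2.11
stack GU GU -0.50
stack GU UG 1.30
stack UG AU -1.00
stack UG UA -0.55
stack UG CG -1.53
stack UG GC -1.41
stack UG GU 0.30
stack UG UG -0.50
hairpin 3 5.4
hairpin 4 5.6
hairpin 5 5.7
hairpin 6 5.4
hairpin 7 6.0
hairpin 8 5.5
hairpin 9 6.4
bulge 1 3.8
bulge 2 2.8
bulge 3 3.2
internal 2 1.7
internal 3 1.8
internal 4 1.1
internal 5 2.0
internal 6 2.0
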