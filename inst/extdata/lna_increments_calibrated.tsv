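# Locked-nucleic-acid modification increments, per LNA base and per adjacent
# dinucleotide stack (an internal LNA modifies both flanking stacks, a
# terminal LNA one; a stack flanked by two LNA bases receives both
# contributions). dH_inc in kcal/mol, dS_inc in cal/(mol K).
# SYNTHETIC / CALIBRATED table: these are NOT the published McTigue et al.
# (2004) single-substitution parameters, which were unavailable to this
# package. They are the package's own per-base increments, fitted once
# against the printed melting-temperature anchors of the reference clamp and
# primer designs under the default conditions (240 mM monovalent cation,
# 0.8 uM oligo) and then frozen; see the methods vignette. The fitted set
# reproduces the qualitative literature ordering (pyrimidine LNAs stabilize
# more than purine LNAs): single-substitution effects on a 22-mer are about
# +1.4 (C), +0.6 (T), +0.3 (A), +0.1 (G) degC.
# table version: 1.0
base	dH_inc	dS_inc
A	-2.2	-6.23
C	-2.2	-5.44
G	-2.2	-6.40
T	-2.2	-6.02
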