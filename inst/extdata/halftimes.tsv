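# Intrinsic deamidation half-times of Asn-(N+1) dipeptides in unstructured
# model peptides (pentapeptide series, pH 7.4, 37 degC), in days.
# The N+1 residue dominates the succinimide-formation rate: Gly is by far
# the fastest, branched beta-carbons (Val, Ile) the slowest.
# Pro is deliberately absent: the tertiary backbone amide of proline blocks
# the nucleophilic attack that forms the succinimide, so the mechanism this
# table describes does not apply; lookups for Asn-Pro fail explicitly.
# Columns: residue <TAB> t50_days <TAB> source
residue	t50_days	source
G	1.03	pentapeptide series pH 7.4 37C
H	9.54	pentapeptide series pH 7.4 37C
S	15.8	pentapeptide series pH 7.4 37C
A	24.6	pentapeptide series pH 7.4 37C
D	32.6	pentapeptide series pH 7.4 37C
T	46.4	pentapeptide series pH 7.4 37C
C	55.4	pentapeptide series pH 7.4 37C
K	59.1	pentapeptide series pH 7.4 37C
R	60.5	pentapeptide series pH 7.4 37C
N	61.6	pentapeptide series pH 7.4 37C
M	66.0	pentapeptide series pH 7.4 37C
Q	70.0	pentapeptide series pH 7.4 37C
E	76.4	pentapeptide series pH 7.4 37C
F	78.4	pentapeptide series pH 7.4 37C
W	99.5	pentapeptide series pH 7.4 37C
Y	100.4	pentapeptide series pH 7.4 37C
L	130.0	pentapeptide series pH 7.4 37C
V	251.0	pentapeptide series pH 7.4 37C
I	507.0	pentapeptide series pH 7.4 37C
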