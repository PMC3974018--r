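# Compact nearest-neighbor free-energy table, kcal/mol at 310.15 K.
#
# Grammar: '#' starts a comment; sections are introduced by a bracketed
# header and contain whitespace-separated records.
#   [stack]      OUTER INNER dG     stacked pairs: OUTER = (i,j), INNER = (i+1,j-1),
#                                   both written 5'-base then 3'-base
#   [hairpin]    SIZE dG            loop initiation by number of unpaired bases
#   [bulge]      SIZE dG
#   [internal]   SIZE dG            SIZE = total unpaired on both sides
#   [multiloop]  offset|branch|unpaired dG
#   [misc]       terminal_au | lxc | gas_constant | temperature  VALUE
# Loop sizes beyond the largest tabulated entry are extrapolated as
# dG(size) = dG(max) + lxc * ln(size/max).
# Thermodynamic symmetry holds: stack(P,Q) = stack(flip(Q),flip(P)).

[stack]
AU AU -0.93
AU CG -2.24
AU GC -2.08
AU UA -1.10
AU GU -0.55
AU UG -1.36
CG AU -2.11
CG CG -3.26
CG GC -2.36
CG UA -2.08
CG GU -1.41
CG UG -2.11
GC AU -2.35
GC CG -3.42
GC GC -3.26
GC UA -2.24
GC GU -1.53
GC UG -2.51
UA AU -1.33
UA CG -2.35
UA GC -2.11
UA UA -0.93
UA GU -1.00
UA UG -1.27
GU AU -1.27
GU CG -2.51
GU GC -2.11
GU UA -1.36
GU GU -0.50
GU UG -0.40
UG AU -1.00
UG CG -1.53
UG GC -1.41
UG UA -0.55
UG GU -0.20
UG UG -0.50

[hairpin]
3 5.70
4 5.60
5 5.60
6 5.40
7 5.57
8 5.71
9 5.84
10 5.95
11 6.05
12 6.15
13 6.23
14 6.31
15 6.39
16 6.46
17 6.52
18 6.59
19 6.64
20 6.70
21 6.75
22 6.80
23 6.85
24 6.90
25 6.94
26 6.98
27 7.02
28 7.06
29 7.10
30 7.14

[bulge]
1 3.80
2 2.80
3 3.20
4 3.60
5 4.00
6 4.40
7 4.57
8 4.71
9 4.84
10 4.95
11 5.05
12 5.15
13 5.23
14 5.31
15 5.39
16 5.46
17 5.52
18 5.59
19 5.64
20 5.70
21 5.75
22 5.80
23 5.85
24 5.90
25 5.94
26 5.98
27 6.02
28 6.06
29 6.10
30 6.14

[internal]
2 4.10
3 5.10
4 4.90
5 5.30
6 5.70
7 5.87
8 6.01
9 6.14
10 6.25
11 6.35
12 6.45
13 6.53
14 6.61
15 6.69
16 6.76
17 6.82
18 6.89
19 6.94
20 7.00
21 7.05
22 7.10
23 7.15
24 7.20
25 7.24
26 7.28
27 7.32
28 7.36
29 7.40
30 7.44

[multiloop]
offset 3.40
branch 0.40
unpaired 0.00

[misc]
terminal_au 0.50
lxc 1.079
gas_constant 0.0019872
temperature 310.15
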