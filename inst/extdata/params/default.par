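# wuchtyfold default nearest-neighbor parameter set (kcal/mol, 37 C)
# Compact Turner-style tables: stacking for all six pair types, loop
# initiation to length 30, affine multibranch model, terminal AU/GU penalty,
# logarithmic loop extrapolation beyond length 30.

[stack]
# rows = closing (outer) pair, columns = stacked (inner) pair
# order: AU CG GC UA GU UG
-0.9 -2.2 -2.1 -1.1 -0.6 -1.4
-2.1 -3.3 -2.4 -2.1 -1.4 -2.1
-2.4 -3.4 -3.3 -2.2 -1.5 -2.5
-1.3 -2.4 -2.1 -0.9 -1.0 -1.3
-1.3 -2.5 -2.1 -1.4 -0.5  1.3
-1.0 -1.5 -1.4 -0.6  0.3 -0.5

[hairpin]
Inf Inf 5.4 5.6 5.7 5.4 6.0 5.5 6.4 6.5
6.6 6.7 6.8 6.9 6.9 7.0 7.1 7.1 7.2 7.2
7.3 7.3 7.4 7.4 7.5 7.5 7.5 7.6 7.6 7.7

[bulge]
3.8 2.8 3.2 3.6 4.0 4.4 4.6 4.7 4.8 4.9
5.0 5.1 5.2 5.3 5.4 5.4 5.5 5.5 5.6 5.7
5.7 5.8 5.8 5.8 5.9 5.9 6.0 6.0 6.0 6.1

[internal]
Inf 1.5 1.8 2.0 2.2 2.5 2.6 2.8 2.9 3.0
3.1 3.1 3.2 3.3 3.3 3.4 3.4 3.5 3.5 3.6
3.6 3.7 3.7 3.7 3.8 3.8 3.8 3.9 3.9 3.9

[multiloop]
# closing (a)  per-branch (b)  per-unpaired (c)
3.4 0.4 0.0

[misc]
# terminalAU  loopExtrapolation (1.75 * R * T)  temperature (K)
0.5 1.08 310.15
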