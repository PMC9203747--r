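# Single-cell Drosophila melanogaster segment polarity network (N = 17).
# Transcribed from the Boolean model of Albert & Othmer (2003),
# J. Theor. Biol. 223:1-18 (single-cell reduction: the neighbouring-cell
# signals WG_{i+/-1} and hh/HH_{i+/-1} are merged into the external inputs
# nWG and nHH). SLP, nWG and nHH have no regulators and are frozen at
# their initial value. The model has 10 attractors under synchronous
# update.
targets, factors
SLP, SLP
nWG, nWG
nHH, nHH
wg, (CIA & SLP & !CIR) | (wg & (CIA | SLP) & !CIR)
WG, wg
en, nWG & !SLP
EN, en
hh, EN & !CIR
HH, hh
ptc, CIA & !EN & !CIR
PTC, ptc | (PTC & !nHH)
PH, PTC & nHH
SMO, !PTC | nHH
ci, !EN
CI, ci
CIA, CI & (SMO | nHH)
CIR, CI & !SMO & !nHH
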