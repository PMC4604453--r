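# Shared fixtures: small synthetic systems with exact ground truth.

# Decaying essential-dynamics-like spectrum (nm^2).
decaySpectrum <- function(n, lambda1 = 0.1, tau = 8) {
  lambda1 * exp(-(seq_len(n) - 1) / tau)
}

# A mean structure, its rigid-body modes, and a spectral basis orthogonal to
# them (so prescribed spectra survive superposition).
internalBasis <- function(nAtoms, k, seed = 1L) {
  mn <- e2dyn:::.caTrace(nAtoms, seed = seed)
  rigid <- e2dyn:::.rigidBasis(coords(mn))
  list(mean = mn,
       basis = randomOrthonormalBasis(3L * nAtoms, k = k, seed = seed,
                                      orthogonalTo = rigid))
}

# Quietly read a PDB ensemble (readPDBModels logs atom counts via message()).
readPDBQuiet <- function(path) suppressMessages(readPDBModels(path))

# Hand-written alignment embedding the six CES/D-site motif classes.
# Reference record: Ser at ungapped position 5 followed by Pro (SP motif).
cesFixtureMSA <- function() {
  MSA(c(
    hHR6A_like = "MKLQSPWTRA",   # S at pos 5, +1 P  -> SP, Cdk consensus
    Ubc1_like  = "MKLQDPWTRA",   # D ... P           -> DP
    fam14_like = "MKLQEPWTRA",   # E ... P           -> EP
    fam15_like = "MKLQEAWTRA",   # E ... A           -> EA
    fam15b_like= "MKLQEKWTRA",   # E ... other       -> E
    uev_like   = "MKLQAPWTRA"    # A                 -> other
  ))
}
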