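# Small shared systems built in code at test time.

ref_params <- dpd_params()
ref_topology <- chain_topology(3, 3, 6)

# a small thermalised solvent box
small_fluid <- function(box = 5, seed = 1) {
  init_velocities(solvent_system(box, seed = seed), 1, seed = seed + 1)
}

# a frame of two isolated bonded beads at separation r0 along x, at rest
bonded_pair_frame <- function(r0 = 0.5, box = 10) {
  dpd_frame(rbind(c(5 - r0 / 2, 5, 5), c(5 + r0 / 2, 5, 5)),
            species = c("S", "S"), box = box,
            bonds = matrix(c(1L, 2L), 1, 2))
}

# interactions with every amplitude equal (neutral medium)
neutral_interactions <- interaction_matrix(aAS = 25, aCS = 25, aAB = 25,
                                           aBS = 25)
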