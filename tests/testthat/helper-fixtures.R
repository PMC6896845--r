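# Shared fixtures, all generated in code.

full_kill <- function(slope = 1, ec50 = 1, top = 1, bottom = 0) {
  list(top = top, bottom = bottom, ec50 = ec50, slope = slope)
}

# noise-free self-combination (sham) checkerboard on the default ladder
sham_matrix <- function(slope = 1, ...) {
  p <- full_kill(slope)
  simulate_dose_matrix(surface_spec(drugA = p, drugB = p,
                                    interaction = "loewe_additive", ...))
}

# 20-position chip (4 x 5) for image tests
tiny_layout <- function() {
  build_default_layout(n_compounds = 2, doses = dose_ladder(20, 3, 3),
                       replicates = 2, n_negative = 2, n_positive = 2,
                       capacity = 20, grid = c(4, 5))
}

default_doses <- function() dose_ladder(20, 3, 6)$concentrations
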