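# shared fixtures, built in code

# tabulated coherent scattering lengths (fm) used by the material oracles
b_C <- 6.6460
b_H <- -3.7390
b_D <- 6.6710
b_O <- 5.8030

# a small instrument for fast fit tests
tiny_instrument <- function(n = 60) {
  nr_instrument(q_grid = exp(seq(log(0.01), log(0.25), length.out = n)))
}

# random physically plausible slab stack for optics property tests
random_stack <- function(n_layers) {
  slab_profile(
    thickness = runif(n_layers, 5, 200),
    sld = runif(n_layers, -0.5, 9),
    roughness = runif(n_layers, 0, 8),
    fronting_sld = 2.07,
    backing_sld = sample(c(-0.56, 6.38, runif(1, 0, 7)), 1),
    backing_roughness = runif(1, 0, 8))
}

# membrane z-window of a model's slab profile: from the top of the SAM
# (start of the water gap) to the backing
membrane_window <- function(model) {
  lo <- sum(model$substrate$thickness)
  hi <- lo + model$water_gap + model$t_inner_head + model$t_inner_tail +
    model$t_outer_tail + model$t_core +
    (if (is.null(model$protein)) 0 else model$protein$thickness)
  c(lo, hi)
}
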