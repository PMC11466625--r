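# small fixtures shared across tests

tiny_construct <- function(seed = 1, dimension = 2) {
  build_construct(dimension, counts = list(axial = 24, psm = 30, pd = 4,
                                           posterior = 10), seed = seed)
}

# a hand-laid state with known positions (no jitter), for readout tests
hand_state <- function() {
  data.frame(
    id = 1:8,
    type = c("AXIAL", "AXIAL", "AXIAL", "AXIAL", "AXIAL",
             "PSM", "PSM", "POSTERIOR"),
    x = c(1, 2, 3, 4, 5, 12, 12, 14),
    y = c(0, 0, 0, 0, 0, 0.1, 5, 0),
    radius = 0.5,
    adhesion_distance = c(rep(0.55, 5), 0.625, 0.625, 0.55))
}

quick_params <- function(...) mechanics_params(...)

frozen_params <- function() {
  mechanics_params(repulsion = c(AXIAL = 0, PSM = 0, POSTERIOR = 0),
                   adhesion = c(AXIAL = 0, PSM = 0, POSTERIOR = 0),
                   motility = c(AXIAL = 0, PSM = 0, POSTERIOR = 0),
                   boundary_repulsion = 0,
                   repulsion_pairs = NULL, adhesion_pairs = NULL)
}
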