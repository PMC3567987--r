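# Shared fixtures: built in code, deterministic.

lacI_pfm <- function(zeta = 1) build_pfm(lacI_sites(), zeta = zeta)

# Small genome with the O1 operator planted mid-sequence.
small_lac_genome <- function(length = 20000, seed = 101,
                             pos = round(length / 2)) {
  g <- synthesize_genome(length, seed = seed)
  plant_site(g, lacI_sites(FALSE)[["O1"]], pos, "O1")
}

# Single-species flat-landscape configuration (non-cognate walker) used by
# the renewal-theory and geometric-law oracles.
flat_config <- function(M = 5000, copies = 1, k_assoc = 2000,
                        p_unbind = 0.02, tau0 = 1e-5, duration = 2,
                        footprint = 23L, ...) {
  g <- synthesize_genome(M, seed = 5)
  sp <- tf_species("walker", copies, footprint = footprint, tau0 = tau0,
                   k_assoc = k_assoc, p_unbind = p_unbind, cognate = FALSE)
  sim_config(g, list(sp), duration = duration, ...)
}
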