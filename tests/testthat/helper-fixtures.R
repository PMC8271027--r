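# shared fixtures, all built in code

mini_pdb_path <- function() {
  system.file("extdata", "mini_helix_synthetic.pdb", package = "pepxkit")
}

# independent reimplementation of the fast-exchange dispersion curve, used
# as the oracle against the package's forward model and fitters
oracle_luz_meiboom <- function(nu, r2_0, kex, phi) {
  sapply(nu, function(v) {
    if (v == 0) return(r2_0 + phi / kex)
    x <- kex / (4 * v)
    r2_0 + (phi / kex) * (1 - tanh(x) / x)
  })
}

# ten-residue hand-set peak list pair (reference intensity, perturbed
# intensity); statistics frozen from hand computation in the tests
hand_peak_pair <- function() {
  ids <- sprintf("%s%d", c("T", "L", "N", "A", "R", "E", "D", "I", "V", "K"),
                 141:150)
  ref <- peak_list(ids, delta_h = seq(7, 9.7, by = 0.3),
                   delta_n = seq(110, 128, by = 2),
                   intensity = rep(100, 10), provenance = "ref")
  pert_int <- c(20, 100, 95, 105, 90, 110, 100, 85, 100, 95)
  pert <- peak_list(ids, delta_h = seq(7, 9.7, by = 0.3),
                    delta_n = seq(110, 128, by = 2),
                    intensity = pert_int, provenance = "pert")
  list(reference = ref, perturbed = pert, ratios = pert_int / 100)
}
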