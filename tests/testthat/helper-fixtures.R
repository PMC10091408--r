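# Shared fixtures, built lazily once per test run and cached across files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

cg5_duplex <- function() {
  fixture("cg5", function() build_duplex(helix_spec("CGCGCGCGCG",
                                                    inclination = 18.75)))
}

# small duplex for fast geometric tests
cg3_duplex <- function() {
  fixture("cg3", function() build_duplex(helix_spec("CGCGCG",
                                                    inclination = 18.75)))
}

# a large single-frame ion sample around the CG duplex, two shells, no bulk
shell_sample <- function() {
  fixture("shell_sample", function() {
    m <- cg5_duplex()
    spec <- atmosphere_spec(shell_centers = c(3.4, 6.2),
                            shell_widths = c(0.3, 0.3),
                            shell_weights = c(0.5, 0.5), bulk_fraction = 0,
                            n_ions = 10000, seed = 42)
    list(model = m, spec = spec,
         pos = sample_atmosphere(m, spec, n_ions = 10000))
  })
}

# minimal hand-built model: one nucleic residue plus ions at given positions
point_model <- function(rna_xyz, ion_xyz = NULL, box = NULL) {
  n <- nrow(rna_xyz)
  atoms <- data.frame(serial = seq_len(n), name = paste0("C", seq_len(n)),
                      element = "C", chain = "A", resid = 1L, resname = "G",
                      icode = "", x = rna_xyz[, 1], y = rna_xyz[, 2],
                      z = rna_xyz[, 3], stringsAsFactors = FALSE)
  m <- rna_model(atoms, box = box)
  if (!is.null(ion_xyz)) m <- add_ions(m, ion_xyz, "K+")
  m
}

random_rotation <- function() {
  a <- stats::rnorm(3)
  helixion:::rot_axis(a, stats::runif(1, 0, pi))
}
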