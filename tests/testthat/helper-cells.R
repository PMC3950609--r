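# shared fixtures, built once per run

.cache <- new.env(parent = emptyenv())

# the reference cell discretized for the cable solver
fixture_morph <- function() {
  if (is.null(.cache$fixture)) .cache$fixture <- discretize(reference_fixture(), 40)
  .cache$fixture
}

write_swc_text <- function(lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}

# single-cylinder soma morphology (L = d) built through the SWC reader
soma_only_morph <- function(diameter = 20) {
  read_swc(write_swc_text(sprintf("1 1 0 0 0 %.8f -1", diameter / 2)))
}

# distribution table with every fixed active conductance removed (leak only)
passive_table <- function() {
  tab <- distribution_table()
  tab$fixed[c("na", "ca", "k", "ka", "kca_max"), ] <- 0
  tab$socb[] <- 0
  tab
}

# triples that classify as OFF on the reference cell
OFF_T_TRIPLE <- c(2.33e-5, 2.7e-4, 1e-11)
OFF_S_TRIPLE <- c(3e-5, 4e-4, 1e-9)

no_stim_protocol <- function(tstop) {
  rgcsim:::custom_protocol(
    data.frame(t_start = numeric(0), duration = numeric(0),
               amplitude = numeric(0)), tstop = tstop)
}

# an rgc_recording built from a raw trace, for analysis-operator tests
fake_recording <- function(v, dt, steps = NULL) {
  proto <- rgcsim:::custom_protocol(
    if (is.null(steps)) data.frame(t_start = numeric(0), duration = numeric(0),
                                   amplitude = numeric(0)) else steps,
    tstop = (length(v) - 1) * dt)
  structure(list(time = (seq_along(v) - 1) * dt, v = cbind(soma = v), dt = dt,
                 stim = numeric(length(v)), protocol = proto,
                 sites = c(soma = 1L), metadata = list()),
            class = "rgc_recording")
}
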