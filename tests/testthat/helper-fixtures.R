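# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_pulse <- saturation_pulse()
default_scanner <- scanner_config()

# effectively water-only tissue: vanishing solute pools, no exchange
water_only_tissue <- function(t1 = 2, t2 = 0.06) {
  th <- (param_bounds()$lower + param_bounds()$upper) / 2
  th[1] <- t1; th[2] <- t2
  th[seq(3, 20, by = 3)] <- 1e-12   # all solute fs
  th[seq(4, 20, by = 3)] <- 0       # all solute ksw
  tissue_from_params(th)
}

# small paired dataset reused across tests
small_dataset <- function() fixture("small_dataset", function() {
  generate_dataset(40, seed = 7)
})

# tiny model configs keep gradient/shape tests fast
tiny_config <- function(arch, dropout = 0) {
  model_config(arch, input_len = 5, output_len = 4, hidden_size = 6,
               num_layers = 2, tcn_channels = 3, tcn_dilations = c(1, 2),
               dropout = dropout)
}
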