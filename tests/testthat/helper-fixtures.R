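# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# small default landscape (all five binding drivers active)
small_landscape <- function() {
  if (is.null(.fixture_env$land)) {
    .fixture_env$land <- synthetic_landscape(
      generator_config(nrow = 100, ncol = 100, cell_size = 25, seed = 2)
    )
  }
  .fixture_env$land
}

small_table <- function() {
  if (is.null(.fixture_env$tab)) {
    land <- small_landscape()
    .fixture_env$tab <- stack_to_table(land$stack, land$alnus$fcover,
                                       land$salix$fcover)
  }
  .fixture_env$tab
}

# tiny driver table with independent standard-normal drivers
iid_driver_table <- function(n, seed = 1L) {
  set.seed(seed)
  as.data.frame(matrix(rnorm(n * 13L), n, 13L,
                       dimnames = list(NULL, driver_names())))
}
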