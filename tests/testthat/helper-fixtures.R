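# Shared fixtures, built once per test run.

femo <- build_femo_fixture()

single_sulfide <- function(b_iso = 15, n_electrons = 18, cell = 12) {
  structure_model(
    tibble::tibble(
      name = "S1", element = "S", x = cell / 2, y = cell / 2, z = cell / 2,
      b_iso = b_iso, n_electrons = n_electrons
    ),
    cell = c(rep(cell, 3), 90, 90, 90)
  )
}

# Common grid box so maps of different models are directly comparable.
femo_box <- local({
  lo <- c(min(femo$x), min(femo$y), min(femo$z)) - 4
  hi <- c(max(femo$x), max(femo$y), max(femo$z)) + 4
  list(origin = lo, dims = ceiling((hi - lo) / 0.3) + 1)
})

femo_map_03 <- synthesize_map(map_spec(femo, grid_spacing = 0.3))

atom_pos <- function(model, name) {
  i <- match(name, model$name)
  c(model$x[i], model$y[i], model$z[i])
}
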