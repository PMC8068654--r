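noise_grid <- function(seed, n = 32, cell = 9.6) {
  set.seed(seed)
  density_grid(array(rnorm(n^3), c(n, n, n)), c(rep(cell, 3), 90, 90, 90))
}

point_model <- function(p, cell = 9.6) {
  structure_model(
    tibble::tibble(name = "X1", element = "C",
      x = p[1], y = p[2], z = p[3]),
    cell = c(rep(cell, 3), 90, 90, 90)
  )
}

test_that("a zero difference map scores zero; signs separate excursions", {
  flat <- density_grid(array(0, c(24, 24, 24)), c(12, 12, 12, 90, 90, 90))
  m <- point_model(c(6, 6, 6), cell = 12)
  sc0 <- region_difference_score(flat, m, "X1", d_min = 1.8)
  expect_equal(sc0$rszd, 0)

  # pure positive blob inside the region on a noise background
  g <- noise_grid(5, n = 40, cell = 12)
  blob <- g$values
  ctr <- c(6, 6, 6)
  sp <- grid_spacing(g)
  idx <- round((ctr - g$origin) / sp) + 1
  blob[idx[1] + (-2:2), idx[2] + (-2:2), idx[3] + (-2:2)] <-
    blob[idx[1] + (-2:2), idx[2] + (-2:2), idx[3] + (-2:2)] + 25
  gb <- density_grid(blob, g$cell, g$origin)
  sc <- region_difference_score(gb, point_model(ctr, 12), "X1", d_min = 1.8)
  expect_gt(sc$rszd_pos, 3)
  expect_lt(sc$rszd_neg, 1.5)
  expect_equal(sc$rszd, max(sc$rszd_pos, sc$rszd_neg))

  # sign flip swaps the two scores exactly
  gneg <- density_grid(-blob, g$cell, g$origin)
  scn <- region_difference_score(gneg, point_model(ctr, 12), "X1",
    d_min = 1.8)
  expect_equal(scn$rszd_pos, sc$rszd_neg, tolerance = 1e-10)
  expect_equal(scn$rszd_neg, sc$rszd_pos, tolerance = 1e-10)
})

test_that("adding a positive blob never decreases the positive score", {
  g <- noise_grid(9, n = 36, cell = 10.8)
  m <- point_model(c(5.4, 5.4, 5.4), cell = 10.8)
  base <- region_difference_score(g, m, "X1", d_min = 1.8)
  sp <- grid_spacing(g)
  idx <- round((c(5.4, 5.4, 5.4) - g$origin) / sp) + 1
  for (bump in c(2, 5, 10)) {
    v <- g$values
    v[idx[1], idx[2], idx[3]] <- v[idx[1], idx[2], idx[3]] + bump
    sc <- region_difference_score(density_grid(v, g$cell, g$origin), m,
      "X1", d_min = 1.8)
    expect_gte(sc$rszd_pos, base$rszd_pos - 1e-8)
    base <- sc
  }
})

test_that("the score is calibrated like |Z| on pure noise", {
  g <- noise_grid(101, n = 40, cell = 12)
  set.seed(202)
  meds <- replicate(200, {
    p <- runif(3, 2.5, 9.5)
    region_difference_score(g, point_model(p, 12), "X1", d_min = 1.8)$rszd
  })
  expect_lt(median(meds), 1.5)
})

test_that("the under-electron model scores worse across noise seeds", {
  n2 <- substitute_ligand(femo, "2B", "N2", orientation = c(0, 0, 1))
  sp <- function(m, ...) {
    map_spec(m, grid_spacing = 0.3, box = femo_box, ...)
  }
  calc_s <- synthesize_map(sp(femo))
  calc_n <- synthesize_map(sp(n2))
  wins <- 0L
  for (s in 1:20) {
    obs <- synthesize_map(sp(femo, noise_sd = 0.05, seed = s))
    dmap <- function(calc) {
      density_grid(obs$values - calc$values, obs$cell, obs$origin)
    }
    sc_s <- region_difference_score(dmap(calc_s), femo, "S2B", d_min = 1.8)
    sc_n <- region_difference_score(dmap(calc_n), femo, "S2B", d_min = 1.8)
    wins <- wins + (sc_n$rszd_pos > sc_s$rszd_pos)
  }
  expect_gte(wins, 18)
})

test_that("report aggregation reproduces the published row sums", {
  ref <- nitrogenase_rszd_tables()
  sum_of <- function(ch, mod) {
    rows <- dplyr::filter(ref, chain == ch, model == mod)
    aggregate_report(rows, label = mod)$total
  }
  expect_equal(sum_of("A", "S2- q=-3"), 21.8, tolerance = 1e-9)
  expect_equal(sum_of("A", "N2 q=-1"), 23.0, tolerance = 1e-9)
  expect_equal(sum_of("C", "S2-/S2- q=-3"), 16.3, tolerance = 1e-9)
  expect_equal(sum_of("C", "N2/N2 q=+1"), 23.3, tolerance = 1e-9)
  expect_equal(aggregate_report(dplyr::slice(ref, 0))$total, 0)
})

test_that("model ranking is ascending, tie-stable, and region-checked", {
  ref <- nitrogenase_rszd_tables()
  reports <- dplyr::filter(ref, chain == "C") |>
    dplyr::group_split(model) |>
    purrr::map(~ aggregate_report(.x, label = .x$model[1]))
  ranked <- rank_models(reports)
  expect_equal(ranked$model[1], "S2-/S2- q=-3")
  expect_equal(ranked$total[1], 16.3, tolerance = 1e-9)
  expect_equal(ranked$model[nrow(ranked)], "N2/N2 q=+1")
  expect_true(all(diff(ranked$total) >= 0))

  dup <- rank_models(list(reports[[1]], reports[[1]]))
  expect_equal(nrow(dup), 2)
  expect_equal(dup$total[1], dup$total[2])

  a_rep <- aggregate_report(
    dplyr::filter(ref, chain == "A", model == "S2- q=-3"), "A")
  expect_error(rank_models(list(reports[[1]], a_rep)), "different region")
})

test_that("ground truth ranks first among synthetic candidate models", {
  variants <- list(
    truth = femo,
    n2 = substitute_ligand(femo, "2B", "N2", orientation = c(0, 0, 1)),
    n2h2 = substitute_ligand(femo, "2B", "N2H2", orientation = c(0, 0, 1))
  )
  sp <- function(m, ...) map_spec(m, grid_spacing = 0.3, box = femo_box, ...)
  calc <- purrr::map(variants, ~ synthesize_map(sp(.x)))
  first <- 0L
  n_seeds <- 20L
  for (s in 1:n_seeds) {
    obs <- synthesize_map(sp(femo, noise_sd = 0.05, seed = 1000 + s))
    reports <- purrr::imap(calc, function(cm, nm) {
      d <- density_grid(obs$values - cm$values, obs$cell, obs$origin)
      aggregate_report(
        region_difference_score(d, femo, "S2B", d_min = 1.8,
          group_name = "2B"),
        label = nm
      )
    })
    ranked <- rank_models(unname(reports))
    first <- first + (ranked$model[1] == "truth")
  }
  expect_gte(first, 18L)
})
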