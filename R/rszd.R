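# chi-square excursion statistic -> standard-normal-equivalent score.
# x is the (scaled) sum of squared sigma values over one sign; df the
# effective number of independent samples contributing to that sign.
.chisq_to_z <- function(x, df) {
  if (df <= 0 || x <= 0) return(0)
  logp <- pchisq(x, df, lower.tail = FALSE, log.p = TRUE)
  z <- qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  max(z, 0)
}

#' Real-space difference-density Z score for an atom group
#'
#' Scores how much signed difference density a region holds, on a
#' |Z|-like scale.  Sigma-unit values are collected at all voxels within
#' `radius` of any region atom; the positive and negative excursions are
#' summed as chi-square statistics, each rescaled by the effective number
#' of independent samples `n_eff = n_voxels * voxel_volume / d_min^3`
#' (adjacent voxels of a d_min-limited map are strongly correlated, so a
#' voxel carries `voxel_volume / d_min^3` of an independent observation),
#' and converted to a standard-normal-equivalent score.  Positive scores
#' flag missing electrons in the model (e.g. an N2 placed where sulfide
#' belongs), negative scores excess electrons; the reported `rszd` is the
#' larger of the two.
#'
#' @param diff a signed difference [density_grid()] (model-minus-observed
#'   convention does not matter; see `rszd_pos`/`rszd_neg`).
#' @param model a [structure_model()] supplying the region atoms.
#' @param atoms atom names defining the region (union of spheres).
#' @param radius per-atom sphere radius, angstrom.
#' @param d_min resolution of the map, angstrom (1.83 matches the
#'   nitrogenase data this package was built around).
#' @param group_name label for the report row.
#' @param chain optional chain to disambiguate atom names.
#' @return one-row tibble: `group`, `n_voxels`, `n_eff`, `rszd_pos`,
#'   `rszd_neg`, `rszd = max(rszd_pos, rszd_neg)`.
#' @export
region_difference_score <- function(diff, model, atoms, radius = 1.05,
                                    d_min = 1.83, group_name = "region",
                                    chain = NULL) {
  if (length(atoms) == 0) abort("empty region: no atoms given")
  if (is.null(d_min) || !is.finite(d_min) || d_min <= 0) {
    abort("d_min must be a positive resolution in angstrom")
  }
  idx <- match_atoms(model, atoms, chain = chain)
  xyz <- atom_xyz(model)[idx, , drop = FALSE]
  sp <- grid_spacing(diff)
  dims <- dim(diff$values)
  lo <- pmax(floor((apply(xyz, 2, min) - radius - diff$origin) / sp) + 1, 1)
  hi <- pmin(ceiling((apply(xyz, 2, max) + radius - diff$origin) / sp) + 1,
    dims)
  if (any(lo > hi)) abort("region lies outside the map volume")
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  px <- diff$origin[1] + (ix - 1) * sp[1]
  py <- diff$origin[2] + (iy - 1) * sp[2]
  pz <- diff$origin[3] + (iz - 1) * sp[3]
  keep <- array(FALSE, dim = c(length(ix), length(iy), length(iz)))
  for (j in seq_len(nrow(xyz))) {
    r2 <- outer(outer((px - xyz[j, 1])^2, (py - xyz[j, 2])^2, "+"),
      (pz - xyz[j, 3])^2, "+")
    keep <- keep | (r2 <= radius^2)
  }
  if (!any(keep)) abort("no voxel centers inside the region")
  raw <- diff$values[ix, iy, iz][keep]
  # a constant (e.g. all-zero) difference map has no excursions at all
  v <- if (diff$rmsd > 0) map_sigma(diff, raw) else rep(0, length(raw))
  n_vox <- sum(keep)
  f <- grid_voxel_volume(diff) / d_min^3
  n_eff <- n_vox * f
  score <- function(x) .chisq_to_z(f * sum(x^2), n_eff / 2)
  pos <- score(v[v > 0])
  neg <- score(v[v < 0])
  tibble(
    group = group_name, n_voxels = n_vox, n_eff = n_eff,
    rszd_pos = pos, rszd_neg = neg, rszd = max(pos, neg)
  )
}

#' Aggregate region scores into a model-comparison report
#'
#' @param scores tibble of region rows with at least `group` and `rszd`
#'   (e.g. stacked [region_difference_score()] rows, or published
#'   per-region score columns).
#' @param label model label (e.g. `"S2-"`, `"N2 q=-1"`).
#' @return a `model_comparison` object: the rows plus their `total`
#'   (sum of `rszd`, the single-number model-quality summary).
#' @export
aggregate_report <- function(scores, label = "model") {
  scores <- as_tibble(scores)
  if (nrow(scores) > 0) stopifnot(all(c("group", "rszd") %in% names(scores)))
  out <- list(
    label = label, rows = scores,
    total = if (nrow(scores)) sum(scores$rszd) else 0
  )
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> ", x$label, ": total RSZD ",
    signif(x$total, 4), " over ", nrow(x$rows), " regions\n", sep = "")
  print(x$rows)
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) {
  x$rows |> mutate(model = x$label, .before = 1)
}

#' @export
glance.model_comparison <- function(x, ...) {
  tibble(
    model = x$label, n_regions = nrow(x$rows), total = x$total,
    max_region = if (nrow(x$rows)) max(x$rows$rszd) else 0
  )
}

#' Rank candidate models by total difference-density score
#'
#' Orders model-comparison reports by ascending total RSZD (best-fitting
#' model first); ties are broken by the largest single-region score, then
#' by label.
#'
#' @param reports list of `model_comparison` objects over identical region
#'   lists.
#' @return tibble with `rank`, `model`, `total`, `max_region`.
#' @export
rank_models <- function(reports) {
  stopifnot(length(reports) >= 2)
  groups <- purrr::map(reports, ~ .x$rows$group)
  if (length(unique(purrr::map_chr(groups, paste, collapse = "|"))) != 1) {
    abort("model reports cover different region lists")
  }
  g <- purrr::map_dfr(reports, glance)
  g |>
    arrange(.data$total, .data$max_region, .data$model) |>
    mutate(rank = row_number(), .before = 1)
}
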