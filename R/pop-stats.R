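#' Summarise a reference population of integrated densities
#'
#' @param values numeric vector (n >= 2), e.g. the per-atom integrated
#'   densities of all sulfur atoms in a structure or cluster.
#' @return one-row tibble: `n`, `mean`, `sd` (sample standard deviation,
#'   n - 1 denominator — the convention that reproduces published Av/SD
#'   table rows from their own per-atom columns).
#' @export
summarize_population <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("population summary needs at least 2 values")
  tibble(n = length(values), mean = mean(values), sd = sd(values))
}

#' Z-scores of integrated densities against a reference population
#'
#' Standardizes each `rho` by a reference population's mean and sample
#' standard deviation.  The reference may be the targets' own population
#' (leave-in convention: a cluster z-score for an atom is computed against
#' statistics that include the atom itself) or any external population.
#'
#' @param data tibble with a `rho` column (e.g. from
#'   [integrate_selection()]), or a numeric vector.
#' @param reference one-row tibble from [summarize_population()]; defaults
#'   to the population of `data$rho` itself.
#' @param col name of the output z column.
#' @return `data` with the z column appended (or a numeric vector input
#'   returns a tibble with `rho` and z).
#' @export
pop_zscores <- function(data, reference = NULL, col = "z") {
  if (is.numeric(data)) data <- tibble(rho = as.numeric(data))
  if (is.null(reference)) reference <- summarize_population(data$rho)
  if (reference$sd <= 0) abort("reference sd must be positive for z-scores")
  data[[col]] <- (data$rho - reference$mean) / reference$sd
  data
}

#' Two-sided significance of a population z-score
#'
#' Probability that a draw from a Student-t distribution with `df` degrees
#' of freedom falls within `|z|` of zero: `1 - 2 * P(T > |z|)`.  With
#' `df = n - 1` this treats an atom's deviation from its n-member reference
#' population as a t statistic; a value of 0.87 at `z = 1.7`, `df = 9` says
#' a deviation of that size is unremarkable in a population of ten.  The
#' Student-t form is a reconstruction of the convention behind published
#' significance values; set `dist = "normal"` for the large-sample version
#' (about 0.91 at z = 1.7).
#'
#' @param z deviation in population sigma units.
#' @param df degrees of freedom (>= 1).
#' @param dist `"t"` (default) or `"normal"`.
#' @return significance in `[0, 1)`.
#' @export
tail_significance <- function(z, df = 9, dist = c("t", "normal")) {
  dist <- match.arg(dist)
  if (dist == "t" && any(df < 1)) abort("df must be >= 1")
  upper <- switch(dist,
    t = pt(abs(z), df, lower.tail = FALSE),
    normal = pnorm(abs(z), lower.tail = FALSE)
  )
  1 - 2 * upper
}

#' Build a two-population integration report
#'
#' Mirrors the layout of published integrated-density tables: one row per
#' atom with the raw integral `rho`, its z-score against all reference
#' atoms in the structure (`rho_all`) and against the atoms of its own
#' cluster/chain (`rho_cluster`), plus per-chain `Av`/`SD` footer rows.
#'
#' @param data tibble with columns `atom`, `chain`, `rho` (e.g. stacked
#'   [integrate_selection()] results for each chain).
#' @param all_reference optional [summarize_population()] row for the
#'   structure-wide reference population; defaults to all rows of `data`.
#' @return list with `rows` (per-atom tibble, z columns `rho_all` and
#'   `rho_cluster`) and `footer` (per-chain Av/SD tibble), of class
#'   `integration_report`.
#' @export
build_integration_report <- function(data, all_reference = NULL) {
  stopifnot(all(c("atom", "chain", "rho") %in% names(data)))
  if (is.null(all_reference)) all_reference <- summarize_population(data$rho)
  rows <- data |>
    pop_zscores(reference = all_reference, col = "rho_all") |>
    group_by(.data$chain) |>
    mutate(
      rho_cluster = (.data$rho - mean(.data$rho)) / sd(.data$rho)
    ) |>
    ungroup()
  footer <- data |>
    group_by(.data$chain) |>
    summarise(n = n(), Av = mean(.data$rho), SD = sd(.data$rho))
  out <- list(rows = rows, footer = footer, all_reference = all_reference)
  class(out) <- "integration_report"
  out
}

#' @export
print.integration_report <- function(x, ...) {
  cat("<integration_report>\n")
  print(x$rows, n = Inf)
  print(x$footer)
  invisible(x)
}

#' @export
tidy.integration_report <- function(x, ...) x$rows

#' @export
glance.integration_report <- function(x, ...) {
  x$footer |>
    tidyr::pivot_wider(
      names_from = "chain", values_from = c("n", "Av", "SD")
    )
}
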