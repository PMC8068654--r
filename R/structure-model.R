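#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange bind_rows group_by summarise
#'   ungroup left_join pull n row_number
#' @importFrom stats sd pt pnorm qnorm pchisq optim rnorm setNames fft
#' @importFrom generics tidy glance augment
NULL

# Atomic numbers for the elements this package meets in practice.
.element_z <- c(
  H = 1, C = 6, N = 7, O = 8, NA_ = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28,
  CU = 29, ZN = 30, SE = 34, MO = 42, W = 74
)

element_electrons <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  z <- unname(.element_z[key])
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  z
}

#' Build a structure model from an atom table
#'
#' A structure model is a tibble of atom records (one row per atom) carrying
#' the unit cell and a label as attributes.  Columns: `serial`, `name`,
#' `element`, `chain`, `residue_name`, `residue_number`, `x`, `y`, `z`
#' (angstrom, orthogonal frame), `occupancy`, `b_iso` (angstrom^2),
#' `u_aniso` (list column of symmetric 3x3 tensors in angstrom^2, or `NULL`
#' entries), and `n_electrons`.  `n_electrons` defaults to the element's
#' atomic number but can be overridden, e.g. 18 for a sulfide S^2- ion.
#'
#' @param atoms data frame with at least `name`, `element`, `x`, `y`, `z`.
#'   Missing optional columns are filled with defaults (chain "A",
#'   occupancy 1, b_iso 15, no anisotropic tensor).
#' @param cell numeric length-6 unit-cell parameters `(a, b, c, alpha, beta,
#'   gamma)` in angstrom and degrees, or `NULL` to derive a padded P1 box.
#' @param label free-text model label.
#' @return a `structure_model` tibble.
#' @export
structure_model <- function(atoms, cell = NULL, label = "model") {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  if (is.null(atoms[["serial"]])) atoms$serial <- seq_len(n)
  if (is.null(atoms[["chain"]])) atoms$chain <- "A"
  if (is.null(atoms[["residue_name"]])) atoms$residue_name <- "LIG"
  if (is.null(atoms[["residue_number"]])) atoms$residue_number <- 1L
  if (is.null(atoms[["occupancy"]])) atoms$occupancy <- 1
  if (is.null(atoms[["b_iso"]])) atoms$b_iso <- 15
  if (is.null(atoms[["u_aniso"]])) atoms$u_aniso <- vector("list", n)
  if (is.null(atoms[["n_electrons"]])) {
    atoms$n_electrons <- element_electrons(atoms$element)
  }
  validate_structure_model(atoms)
  if (is.null(cell)) {
    span <- vapply(atoms[c("x", "y", "z")], function(v) diff(range(v)), 0)
    cell <- c(span + 10, 90, 90, 90)
  }
  atoms <- atoms[c(
    "serial", "name", "element", "chain", "residue_name", "residue_number",
    "x", "y", "z", "occupancy", "b_iso", "u_aniso", "n_electrons"
  )]
  attr(atoms, "cell") <- as.numeric(cell)
  attr(atoms, "label") <- label
  class(atoms) <- c("structure_model", class(atoms))
  atoms
}

validate_structure_model <- function(atoms) {
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    abort("occupancy must lie in [0, 1]")
  }
  if (any(atoms$b_iso < 0)) abort("b_iso must be non-negative")
  if (any(atoms$n_electrons < 0)) abort("n_electrons must be non-negative")
  key <- paste(atoms$chain, atoms$name, atoms$residue_number)
  if (anyDuplicated(key)) {
    abort(paste0(
      "duplicate atom identity (chain, name, residue_number): ",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    ))
  }
  for (u in atoms$u_aniso) {
    if (is.null(u)) next
    if (!isTRUE(all.equal(u, t(u), tolerance = 1e-8))) {
      abort("u_aniso tensors must be symmetric")
    }
    if (min(eigen(u, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort("u_aniso tensors must be positive semidefinite")
    }
  }
  invisible(atoms)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(
    "<structure_model> ", attr(x, "label"), ": ", nrow(x), " atoms, cell ",
    paste(signif(attr(x, "cell"), 5), collapse = " "), "\n",
    sep = ""
  )
  NextMethod()
}

#' Unit-cell accessors
#' @param model a `structure_model`.
#' @return `model_cell()` the length-6 cell; `model_label()` the label.
#' @export
model_cell <- function(model) attr(model, "cell")

#' @rdname model_cell
#' @export
model_label <- function(model) attr(model, "label")

# 3x3 orthogonalization matrix: cartesian = M %*% fractional.
cell_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
    2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), c * cos(be),
    0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, c * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

cell_volume <- function(cell) det(cell_matrix(cell))

atom_xyz <- function(model) {
  cbind(model$x, model$y, model$z)
}

# Select atoms by (chain, name); errors list every missing request.
match_atoms <- function(model, names, chain = NULL) {
  if (!is.null(chain)) {
    idx <- match(paste(chain, names), paste(model$chain, model$name))
  } else {
    idx <- match(names, model$name)
  }
  if (anyNA(idx)) {
    abort(paste0(
      "atom(s) not found in model: ",
      paste(names[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}
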