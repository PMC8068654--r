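#' Read a coordinate model from a PDB-format file
#'
#' Parses fixed-column ATOM/HETATM/ANISOU/CRYST1 records.  ANISOU tensors
#' are converted from the deposited 1e-4 angstrom^2 integer convention to
#' angstrom^2 and matched to their atom by serial number.  Elements are
#' taken from columns 77-78 when present, otherwise inferred from the atom
#' name.
#'
#' @param path file path.
#' @param dialect coordinate-format name; only `"pdb"` is supported.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, dialect = "pdb") {
  if (!identical(dialect, "pdb")) {
    abort(paste0("unsupported coordinate dialect: ", dialect))
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cell <- NULL
  icr <- which(startsWith(rec, "CRYST1"))
  if (length(icr) >= 1) {
    cl <- lines[icr[1]]
    cell <- suppressWarnings(as.numeric(c(
      substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
      substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)
    )))
    if (anyNA(cell)) abort(paste0("malformed CRYST1 record at line ", icr[1]))
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) abort("no ATOM/HETATM records found")
  ai <- which(is_atom)
  al <- format(lines[ai], width = 80)
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    if (anyNA(v)) {
      abort(paste0(
        "malformed ", what, " field in ATOM/HETATM record at line ",
        ai[which(is.na(v))[1]]
      ))
    }
    v
  }
  name <- trimws(substr(al, 13, 16))
  elem <- trimws(substr(al, 77, 78))
  guess <- toupper(sub("[0-9'].*$", "", name))
  guess <- ifelse(guess %in% names(.element_z), guess, substr(guess, 1, 1))
  elem <- ifelse(elem == "", guess, elem)
  atoms <- tibble(
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    element = elem,
    chain = substr(al, 22, 22),
    residue_name = trimws(substr(al, 18, 20)),
    residue_number = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = num(55, 60, "occupancy"),
    b_iso = num(61, 66, "B factor")
  )

  uan <- vector("list", nrow(atoms))
  for (j in which(startsWith(rec, "ANISOU"))) {
    ln <- format(lines[j], width = 80)
    serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    u6 <- suppressWarnings(as.numeric(c(
      substr(ln, 29, 35), substr(ln, 36, 42), substr(ln, 43, 49),
      substr(ln, 50, 56), substr(ln, 57, 63), substr(ln, 64, 70)
    )))
    if (is.na(serial) || anyNA(u6)) {
      abort(paste0("malformed ANISOU record at line ", j))
    }
    k <- match(serial, atoms$serial)
    if (is.na(k)) abort(paste0("ANISOU without matching atom at line ", j))
    u6 <- u6 * 1e-4
    uan[[k]] <- matrix(c(
      u6[1], u6[4], u6[5],
      u6[4], u6[2], u6[6],
      u6[5], u6[6], u6[3]
    ), nrow = 3)
  }
  atoms$u_aniso <- uan
  atoms$n_electrons <- element_electrons(atoms$element)
  structure_model(atoms, cell = cell,
    label = tools::file_path_sans_ext(basename(path)))
}

#' Write a structure model to a PDB-format file
#'
#' Emits CRYST1, HETATM and (where present) ANISOU records.  Anisotropic
#' tensors are encoded with the standard 1e-4 angstrom^2 integer scaling.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  validate_structure_model(model)
  if (any(nchar(model$name) > 4)) {
    abort("atom names longer than 4 characters cannot be encoded")
  }
  cell <- model_cell(model)
  out <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    cell[1], cell[2], cell[3], cell[4], cell[5], cell[6]
  )
  for (i in seq_len(nrow(model))) {
    nm <- model$name[i]
    nm <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    el <- toupper(model$element[i])
    out <- c(out, sprintf(
      "HETATM%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      model$serial[i], nm, substr(model$residue_name[i], 1, 3),
      model$chain[i], model$residue_number[i],
      model$x[i], model$y[i], model$z[i],
      model$occupancy[i], model$b_iso[i], el
    ))
    u <- model$u_aniso[[i]]
    if (!is.null(u)) {
      ui <- round(u * 1e4)
      out <- c(out, sprintf(
        "ANISOU%5d %s %-3s %s%4d  %7d%7d%7d%7d%7d%7d      %2s",
        model$serial[i], nm, substr(model$residue_name[i], 1, 3),
        model$chain[i], model$residue_number[i],
        ui[1, 1], ui[2, 2], ui[3, 3], ui[1, 2], ui[1, 3], ui[2, 3], el
      ))
    }
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
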