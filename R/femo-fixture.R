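# Idealized FeMo-cofactor geometry.  The cofactor is built around the
# central carbide: six belt Fe (Fe2-Fe7) form an eclipsed trigonal prism at
# 2.0 A from C, Fe1 and Mo cap the two ends, three mu2 belt sulfides (S2B
# bridging Fe2/Fe6, S3A bridging Fe3/Fe7, S5A bridging Fe4/Fe5) sit between
# vertically paired Fe, and two triples of mu3 sulfides tie each cap to its
# belt triangle.  Only topology and atom names are meant to be faithful;
# bond lengths use canonical Fe-S ~ 2.3 A and Fe-C ~ 2.0 A values.

.solve_point <- function(anchors, dist, start) {
  f <- function(p) {
    d <- sqrt(colSums((t(anchors) - p)^2))
    sum((d - dist)^2)
  }
  res <- optim(start, f, method = "BFGS",
    control = list(reltol = 1e-14, maxit = 500))
  if (res$value > 1e-8) abort("fixture geometry solve failed to close")
  res$par
}

#' Build an idealized FeMo-cofactor fixture model
#'
#' Returns a one-cluster model with canonical atom names: `MO`, `FE1`-`FE7`,
#' `S1A`-`S5A`, `S1B`-`S4B`, the central carbide `C`, and the Fe1-bound
#' cysteine sulfur `SG` (10 sulfur atoms in total).  Each mu2 belt sulfide
#' bridges exactly two Fe atoms (S2B bridges Fe2 and Fe6); each mu3 sulfide
#' has three metal neighbours.
#'
#' @param chain chain identifier for the atoms.
#' @param b_iso isotropic B factor (angstrom^2) stamped on every atom.
#' @param center cartesian position of the carbide.
#' @return a [structure_model()].
#' @export
build_femo_fixture <- function(chain = "A", b_iso = 15, center = c(0, 0, 0)) {
  d <- 1.3                       # half-height of the Fe belt prism
  r <- sqrt(2.0^2 - d^2)         # belt radius from Fe-C = 2.0 A
  ang <- c(0, 120, 240) * pi / 180
  lower <- t(vapply(ang, function(a) c(r * cos(a), r * sin(a), -d), double(3)))
  upper <- t(vapply(ang, function(a) c(r * cos(a), r * sin(a), +d), double(3)))
  fe1 <- c(0, 0, -2.9)
  mo <- c(0, 0, 2.9)

  # mu2 belt sulfides: outward from the midpoint of each vertical Fe pair,
  # at 2.3 A from both.
  belt_s <- function(p) {
    rad <- sqrt(sum(p[1:2]^2))
    u <- c(p[1:2] / rad, 0)
    (p + c(p[1], p[2], -p[3])) / 2 + u * sqrt(2.3^2 - d^2)
  }
  # mu3 cap sulfides: 2.3 A from the cap metal and its two belt Fe.
  cap_s <- function(m, fa, fb) {
    mid <- (fa + fb) / 2
    out <- mid[1:2] / sqrt(sum(mid[1:2]^2))
    start <- c(mid[1:2] + out * 1.5, m[3] * 0.6)
    .solve_point(rbind(m, fa, fb), c(2.3, 2.3, 2.3), start)
  }

  pos <- rbind(
    MO = mo, FE1 = fe1,
    FE2 = lower[1, ], FE3 = lower[2, ], FE4 = lower[3, ],
    FE6 = upper[1, ], FE7 = upper[2, ], FE5 = upper[3, ],
    C = c(0, 0, 0),
    S2B = belt_s(lower[1, ]),                   # Fe2 - Fe6
    S3A = belt_s(lower[2, ]),                   # Fe3 - Fe7
    S5A = belt_s(lower[3, ]),                   # Fe4 - Fe5
    S1A = cap_s(fe1, lower[1, ], lower[2, ]),   # Fe1, Fe2, Fe3
    S2A = cap_s(fe1, lower[2, ], lower[3, ]),   # Fe1, Fe3, Fe4
    S4A = cap_s(fe1, lower[3, ], lower[1, ]),   # Fe1, Fe4, Fe2
    S1B = cap_s(mo, upper[1, ], upper[2, ]),    # Mo, Fe6, Fe7
    S3B = cap_s(mo, upper[2, ], upper[3, ]),    # Mo, Fe7, Fe5
    S4B = cap_s(mo, upper[3, ], upper[1, ]),    # Mo, Fe5, Fe6
    SG = fe1 + c(0, 0, -2.3)                    # cysteine thiolate on Fe1
  )
  pos <- sweep(pos, 2, center, "+")
  nm <- rownames(pos)
  el <- c(
    MO = "MO", FE1 = "FE", FE2 = "FE", FE3 = "FE", FE4 = "FE", FE5 = "FE",
    FE6 = "FE", FE7 = "FE", C = "C", S2B = "S", S3A = "S", S5A = "S",
    S1A = "S", S2A = "S", S4A = "S", S1B = "S", S3B = "S", S4B = "S",
    SG = "S"
  )[nm]
  nel <- element_electrons(el)
  nel[startsWith(nm, "S")] <- 18  # sulfide / thiolate S^2- electron count
  atoms <- tibble(
    name = nm, element = unname(el), chain = chain,
    residue_name = ifelse(nm == "SG", "CYS", "ICS"),
    residue_number = ifelse(nm == "SG", 2L, 1L),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occupancy = 1, b_iso = b_iso, n_electrons = nel
  )
  ctr <- c(mean(pos[, 1]), mean(pos[, 2]), mean(pos[, 3]))
  structure_model(atoms, cell = c(rep(24, 3), 90, 90, 90),
    label = paste0("femo_", chain)) |>
    shift_model(c(12, 12, 12) - ctr)
}

shift_model <- function(model, delta) {
  model$x <- model$x + delta[1]
  model$y <- model$y + delta[2]
  model$z <- model$z + delta[3]
  model
}

#' Replace a mu2 sulfide site by a diatomic ligand
#'
#' Removes the sulfide at the named belt site and places the replacement
#' centred on the former sulfur position: `"N2"` adds two N atoms 1.10 A
#' apart along `orientation` (14 electrons total), `"N2H2"` additionally adds
#' two H at standard trans-diazene geometry (16 electrons total), and `"S2-"`
#' restores a single 18-electron sulfide (useful for building matched model
#' pairs).
#'
#' @param model a [structure_model()] containing the site atom.
#' @param site one of `"2B"`, `"3A"`, `"5A"`.
#' @param occupant one of `"S2-"`, `"N2"`, `"N2H2"`.
#' @param orientation diatomic axis direction (need not be normalized).
#' @param chain chain holding the site; defaults to the first matching atom.
#' @return a new [structure_model()].
#' @export
substitute_ligand <- function(model, site, occupant = "N2",
                              orientation = c(0, 0, 1), chain = NULL) {
  if (!site %in% c("2B", "3A", "5A")) {
    abort(paste0("unknown mu2 site: ", site, " (expected 2B, 3A or 5A)"))
  }
  sname <- paste0("S", site)
  site_names <- c(sname, paste0("N", site, 1:2), paste0("H", site, 1:2))
  pool <- if (is.null(chain)) model$name else
    ifelse(model$chain == chain, model$name, "")
  occ_idx <- which(pool %in% site_names)
  if (length(occ_idx) == 0) {
    abort(paste0("site ", site, " has no occupant atoms in the model"))
  }
  ctr <- if (sname %in% pool) {
    i <- occ_idx[match(sname, pool[occ_idx])]
    c(model$x[i], model$y[i], model$z[i])
  } else {
    ni <- occ_idx[pool[occ_idx] %in% paste0("N", site, 1:2)]
    c(mean(model$x[ni]), mean(model$y[ni]), mean(model$z[ni]))
  }
  tmpl <- model[occ_idx[1], ]
  rest <- model[-occ_idx, ]
  u <- orientation / sqrt(sum(orientation^2))
  occupant <- toupper(occupant)

  place <- function(name, element, p, nel) {
    a <- tmpl
    a$name <- name
    a$element <- element
    a$x <- p[1]; a$y <- p[2]; a$z <- p[3]
    a$n_electrons <- nel
    a$serial <- max(model$serial) + match(name, place_names)
    a
  }
  if (occupant == "S2-") {
    place_names <- sname
    new <- place(sname, "S", ctr, 18)
  } else if (occupant %in% c("N2", "N2H2")) {
    place_names <- paste0("N", site, 1:2)
    p1 <- ctr - u * 0.55
    p2 <- ctr + u * 0.55
    new <- bind_rows(
      place(place_names[1], "N", p1, 7),
      place(place_names[2], "N", p2, 7)
    )
    if (occupant == "N2H2") {
      # trans-diazene: N-H 1.03 A at ~109 deg from the N-N axis
      perp <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0)
      perp <- perp - sum(perp * u) * u
      perp <- perp / sqrt(sum(perp^2))
      h1 <- p1 - u * 1.03 * cos(71 * pi / 180) + perp * 1.03 * sin(71 * pi / 180)
      h2 <- p2 + u * 1.03 * cos(71 * pi / 180) - perp * 1.03 * sin(71 * pi / 180)
      place_names <- c(place_names, paste0("H", site, 1:2))
      new <- bind_rows(
        new,
        place(place_names[3], "H", h1, 1),
        place(place_names[4], "H", h2, 1)
      )
    }
  } else {
    abort(paste0("unknown occupant: ", occupant))
  }
  out <- bind_rows(rest, new)
  structure_model(out, cell = model_cell(model),
    label = paste0(model_label(model), "_", site, ":", occupant))
}
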