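#' Read a protein structure from a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}), keeps the selected chains, collapses
#' alternate locations to the highest-occupancy copy, and drops waters and
#' other heteroatoms. Only the first model of multi-model files is used.
#'
#' @param path Path to a PDB file.
#' @param chains Character vector of chain identifiers to keep, or `NULL`
#'   for all chains. The selected chain set is treated downstream as a
#'   single rigid body.
#' @param protein_id Identifier for the protein; defaults to the file name
#'   without extension.
#'
#' @return An `atomic_protein` object: a list with `protein_id`, an `atoms`
#'   tibble (one heavy atom per row, with 0-based residue index `res_idx`)
#'   and a `residues` tibble (one residue per row).
#' @export
read_structure <- function(path, chains = NULL, protein_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  # drop hydrogens: element symbol if present, else first alpha of atom name
  elt <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "", substr(gsub("[^A-Za-z].*$", "", at$elety), 1, 1), at$elesy)))
  at <- at[!(elt %in% c("H", "D")), , drop = FALSE]
  if (!is.null(chains)) {
    missing_ch <- setdiff(chains, unique(at$chain))
    if (length(missing_ch)) stop("chain(s) not found in ", path, ": ", paste(missing_ch, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  if (!nrow(at)) stop("no protein atoms after chain selection in ", path)
  icode <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  atoms <- tibble::tibble(
    chain = at$chain, resno = at$resno, icode = icode, resid = at$resid,
    elety = at$elety, x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt)
  )
  # collapse altlocs: keep highest occupancy per (chain, resno, icode, elety)
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-"alt")
  atomic_protein(atoms, protein_id)
}

#' Construct an atomic protein from an atom table
#'
#' @param atoms Tibble with columns `chain`, `resno`, `icode`, `resid`,
#'   `elety`, `x`, `y`, `z` (one heavy atom per row).
#' @param protein_id Protein identifier.
#' @return An `atomic_protein` object with contiguous 0-based `res_idx`.
#' @export
atomic_protein <- function(atoms, protein_id) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  atoms <- tibble::as_tibble(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  res_key <- unique(key)  # file order
  atoms$res_idx <- match(key, res_key) - 1L
  atoms <- atoms[order(atoms$res_idx), , drop = FALSE]
  residues <- atoms |>
    dplyr::group_by(.data$res_idx) |>
    dplyr::summarise(
      chain = .data$chain[1], resno = .data$resno[1], icode = .data$icode[1],
      resid = .data$resid[1], n_atoms = dplyr::n(), .groups = "drop"
    )
  if (any(residues$n_atoms < 1)) stop("residue with no heavy atoms")
  structure(list(protein_id = protein_id, atoms = atoms, residues = residues),
            class = "atomic_protein")
}

#' @export
print.atomic_protein <- function(x, ...) {
  cat("<atomic_protein> ", x$protein_id, ": ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " heavy atoms, chains ",
      paste(unique(x$residues$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Default coarse-graining parameter table
#'
#' Loads the versioned pseudoatom parameter table shipped with the package:
#' per residue type, the number of side-chain beads, the heavy-atom groups
#' whose centroids place them, their charge, and their LJ-type code; per
#' type code, the contact distance scale `sigma` (\eqn{\mathrm{\AA}}) and
#' well-depth scale `eps`.
#'
#' @param path Optional path to an alternative JSON parameter file.
#' @return A list with elements `types` and `residues`.
#' @export
default_cg_params <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "cg_params.json", package = "dockmate")
  jsonlite::read_json(path)
}

#' Coarse-grain an atomic protein into a pseudoatom model
#'
#' Each residue is reduced to one bead at the C\eqn{\alpha} position plus
#' the side-chain beads given by the parameter table (none for Gly, one or
#' two otherwise), placed at the centroid of the table's heavy-atom group.
#' Residues with missing side-chain atoms fall back to C\eqn{\beta}, then
#' C\eqn{\alpha}, with a warning.
#'
#' @param protein An `atomic_protein`.
#' @param params Parameter table, see [default_cg_params()].
#' @return A `cg_protein` object.
#' @export
coarse_grain <- function(protein, params = default_cg_params()) {
  stopifnot(inherits(protein, "atomic_protein"))
  res <- protein$residues
  at <- protein$atoms
  rows <- vector("list", nrow(res))
  fallbacks <- character(0)
  for (i in seq_len(nrow(res))) {
    ri <- res$res_idx[i]
    aa <- res$resid[i]
    spec <- params$residues[[aa]]
    if (is.null(spec)) stop("residue type not in parameter table: ", aa, " (res_idx ", ri, ")")
    ra <- at[at$res_idx == ri, , drop = FALSE]
    ca <- ra[ra$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) {
      warning("no CA atom for residue ", ri, " (", aa, "); using residue centroid")
      ca_xyz <- colMeans(ra[, c("x", "y", "z")])
    } else ca_xyz <- as.numeric(ca[1, c("x", "y", "z")])
    out <- list(bead_row(ri, "CA", ca_xyz, 0, "CA", params))
    for (k in seq_along(spec$sc)) {
      grp <- unlist(spec$sc[[k]]$atoms)
      sel <- ra[ra$elety %in% grp, , drop = FALSE]
      if (nrow(sel) == 0) {
        sel <- ra[ra$elety == "CB", , drop = FALSE]
        if (nrow(sel) == 0) sel <- if (nrow(ca)) ca else ra
        fallbacks <- c(fallbacks, paste0(ri, ":", aa))
      }
      xyz <- colMeans(sel[, c("x", "y", "z")])
      out[[k + 1]] <- bead_row(ri, paste0("SC", k), xyz, spec$sc[[k]]$charge,
                               spec$sc[[k]]$type, params)
    }
    rows[[i]] <- dplyr::bind_rows(out)
  }
  if (length(fallbacks)) {
    warning("missing side-chain atoms for residue(s) ", paste(unique(fallbacks), collapse = ", "),
            "; fell back to CB/CA placement")
  }
  beads <- dplyr::bind_rows(rows)
  cg_protein(protein$protein_id, beads, res[, c("res_idx", "chain", "resno", "icode", "resid")])
}

bead_row <- function(res_idx, role, xyz, charge, type, params) {
  tp <- params$types[[type]]
  if (is.null(tp)) stop("unknown LJ type code: ", type)
  tibble::tibble(res_idx = as.integer(res_idx), role = role,
                 x = xyz[1], y = xyz[2], z = xyz[3],
                 q = as.numeric(charge), type = type,
                 sigma = tp$sigma, eps = tp$eps)
}

#' Construct a coarse-grained protein
#'
#' @param protein_id Identifier.
#' @param beads Tibble with one pseudoatom per row: `res_idx` (0-based),
#'   `role` (`"CA"`, `"SC1"`, `"SC2"`), coordinates `x`,`y`,`z` (\eqn{\mathrm{\AA}}),
#'   charge `q`, LJ `type` code, and resolved `sigma`, `eps`.
#' @param residues Tibble of residue metadata (`res_idx`, `chain`, `resno`,
#'   `icode`, `resid`); generated from `beads` when omitted.
#' @param surface Optional per-residue logical surface mask.
#' @return A `cg_protein` object.
#' @export
cg_protein <- function(protein_id, beads, residues = NULL, surface = NULL) {
  beads <- tibble::as_tibble(beads)
  stopifnot(all(c("res_idx", "role", "x", "y", "z", "q", "type", "sigma", "eps") %in% names(beads)))
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")])))) stop("non-finite bead coordinates")
  if (is.null(residues)) {
    residues <- beads |>
      dplyr::distinct(.data$res_idx) |>
      dplyr::mutate(chain = "A", resno = .data$res_idx + 1L, icode = "", resid = "UNK")
  }
  obj <- structure(list(protein_id = protein_id, beads = beads,
                        residues = tibble::as_tibble(residues), surface = surface),
                   class = "cg_protein")
  obj
}

#' @export
print.cg_protein <- function(x, ...) {
  cat("<cg_protein> ", x$protein_id, ": ", nrow(x$residues), " residues, ",
      nrow(x$beads), " pseudoatoms, total charge ", sum(x$beads$q), "\n", sep = "")
  invisible(x)
}

#' Pseudoatom coordinates of a coarse-grained protein
#' @param protein A `cg_protein`.
#' @return Numeric matrix, one pseudoatom per row.
#' @export
cg_coords <- function(protein) {
  as.matrix(protein$beads[, c("x", "y", "z")])
}

ca_coords <- function(protein) {
  ca <- protein$beads[protein$beads$role == "CA", , drop = FALSE]
  ca <- ca[order(ca$res_idx), , drop = FALSE]
  as.matrix(ca[, c("x", "y", "z")])
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by scattering test points on each atom's solvent-expanded
#' sphere (golden-spiral layout) and counting the points not occluded by any
#' neighbouring sphere.
#'
#' @param xyz Numeric matrix of coordinates (one atom per row).
#' @param radii Per-atom van der Waals radii (\eqn{\mathrm{\AA}}).
#' @param probe Probe radius (default 1.4 \eqn{\mathrm{\AA}}).
#' @param n_points Test points per atom (default 100).
#' @return Per-atom areas in \eqn{\mathrm{\AA}^2}.
#' @export
sasa <- function(xyz, radii, probe = 1.4, n_points = 100) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n, all(is.finite(xyz)), all(radii > 0))
  pts <- sphere_points(n_points)
  r <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + r)^2 & d2 > 0)
    if (!length(nb)) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    sp <- pts * r[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 + (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  areas
}

sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

element_radius <- function(elety) {
  sym <- substr(gsub("^[0-9]*", "", elety), 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  out <- unname(r[sym])
  out[is.na(out)] <- 1.70
  out
}

#' Surface residues by relative solvent accessibility
#'
#' A residue is on the surface iff its SASA in the whole structure divided
#' by the SASA of the residue taken in isolation (same atoms, same probe) is
#' at least `threshold`. Works on atomic proteins (heavy atoms, per-element
#' radii) and on coarse-grained proteins (beads, radius `sigma / 2`).
#'
#' @param protein An `atomic_protein` or `cg_protein`.
#' @param threshold Relative SASA cutoff, default 0.25. A threshold of 0
#'   marks every residue as surface.
#' @param probe Probe radius.
#' @param n_points Test points per atom.
#' @return Logical vector over residues (in `res_idx` order).
#' @export
surface_residues <- function(protein, threshold = 0.25, probe = 1.4, n_points = 100) {
  UseMethod("surface_residues")
}

#' @export
surface_residues.atomic_protein <- function(protein, threshold = 0.25, probe = 1.4, n_points = 100) {
  xyz <- as.matrix(protein$atoms[, c("x", "y", "z")])
  radii <- element_radius(protein$atoms$elety)
  rsasa_mask(xyz, radii, protein$atoms$res_idx, nrow(protein$residues), threshold, probe, n_points)
}

#' @export
surface_residues.cg_protein <- function(protein, threshold = 0.25, probe = 1.4, n_points = 100) {
  xyz <- cg_coords(protein)
  radii <- protein$beads$sigma / 2
  rsasa_mask(xyz, radii, protein$beads$res_idx, nrow(protein$residues), threshold, probe, n_points)
}

rsasa_mask <- function(xyz, radii, res_idx, n_res, threshold, probe, n_points) {
  a <- sasa(xyz, radii, probe, n_points)
  tot <- rep(0, n_res)
  ref <- rep(0, n_res)
  for (ri in unique(res_idx)) {
    sel <- res_idx == ri
    tot[ri + 1] <- sum(a[sel])
    ref[ri + 1] <- sum(sasa(xyz[sel, , drop = FALSE], radii[sel], probe, n_points))
  }
  rs <- ifelse(ref > 0, tot / ref, 0)
  rs >= threshold
}

#' Write a coarse-grained model to a tab-separated file
#'
#' One pseudoatom per row: residue index and author numbering, role,
#' coordinates, charge, type code and LJ scales.
#'
#' @param protein A `cg_protein`.
#' @param path Output path.
#' @export
write_cg_table <- function(protein, path) {
  tab <- dplyr::left_join(protein$beads, protein$residues, by = "res_idx")
  tab <- tab[, c("res_idx", "chain", "resno", "icode", "resid", "role",
                 "x", "y", "z", "q", "type", "sigma", "eps")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coarse-grained model written by [write_cg_table()]
#' @param path Input path.
#' @param protein_id Identifier (defaults to file name).
#' @return A `cg_protein`.
#' @export
read_cg_table <- function(path, protein_id = NULL) {
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE,
                                             colClasses = list(icode = "character", chain = "character")))
  tab$icode[is.na(tab$icode)] <- ""
  res <- dplyr::distinct(tab, .data$res_idx, .data$chain, .data$resno, .data$icode, .data$resid)
  cg_protein(protein_id, tab[, c("res_idx", "role", "x", "y", "z", "q", "type", "sigma", "eps")], res)
}
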