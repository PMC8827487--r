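#' Soft Lennard-Jones / screened-Coulomb docking energy
#'
#' Sums, over all receptor-ligand pseudoatom pairs closer than `cutoff`,
#' \deqn{E_{ij} = B_{ij}/r_{ij}^8 - C_{ij}/r_{ij}^6 + q_i q_j / (15 r_{ij}^2),}
#' i.e. a soft 8-6 repulsive/attractive pair term plus electrostatics with a
#' distance-dependent dielectric \eqn{\epsilon = 15 r}. The charge term only
#' contributes for charged-charged pairs (zero charges vanish identically).
#' Pair coefficients derive from the per-bead LJ scales:
#' \eqn{\sigma_{ij} = (\sigma_i + \sigma_j)/2},
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}},
#' \eqn{B_{ij} = 3\epsilon_{ij}\sigma_{ij}^8}, \eqn{C_{ij} = 4\epsilon_{ij}\sigma_{ij}^6},
#' which puts the pair minimum at \eqn{r = \sigma_{ij}} with depth \eqn{\epsilon_{ij}}.
#'
#' @param receptor,ligand `cg_protein` objects.
#' @param transform `rigid_transform` applied to the ligand.
#' @param cutoff Pair-distance truncation in \eqn{\mathrm{\AA}} (no shifting);
#'   default 12, `Inf` disables.
#' @return Scalar energy (arbitrary coarse-grained units, negative = favourable).
#' @export
pair_energy_maxdo <- function(receptor, ligand, transform = rigid_transform(), cutoff = 12) {
  ctx <- pair_context(receptor, ligand)
  ctx_energy(ctx, transform, energy = "maxdo", cutoff = cutoff)
}

#' Soft 12-6 Lennard-Jones / Coulomb docking energy
#'
#' Sums, over all receptor-ligand pseudoatom pairs closer than `cutoff`,
#' \deqn{E_{ij} = (\sigma_{ij}/r_{ij})^{12} - (\sigma_{ij}/r_{ij})^6 + q_i q_j / (10 r_{ij}),}
#' a 12-6 pair term (no well-depth prefactor) plus electrostatics with a
#' constant dielectric \eqn{\epsilon = 10}. Compared with
#' [pair_energy_maxdo()], repulsion decays faster with distance and the
#' electrostatic contribution persists longer.
#'
#' @inheritParams pair_energy_maxdo
#' @return Scalar energy.
#' @export
pair_energy_iattract <- function(receptor, ligand, transform = rigid_transform(), cutoff = 12) {
  ctx <- pair_context(receptor, ligand)
  ctx_energy(ctx, transform, energy = "iattract", cutoff = cutoff)
}

#' Raw pairwise energy sums from explicit coefficient matrices
#'
#' Low-level workhorses behind [pair_energy_maxdo()] and
#' [pair_energy_iattract()], exposed for testing and for custom bead models:
#' all coefficients are given explicitly, one row per atom of `xyz_a`, one
#' column per atom of `xyz_b`.
#'
#' @param xyz_a,xyz_b Coordinate matrices.
#' @param B,C Repulsive/attractive coefficient matrices (or scalars) for the
#'   8-6 form.
#' @param sigma Contact-distance matrix (or scalar) for the 12-6 form.
#' @param qa,qb Charge vectors.
#' @param cutoff Distance truncation (`Inf` disables).
#' @return Scalar energy.
#' @export
energy_maxdo_raw <- function(xyz_a, xyz_b, B, C, qa, qb, cutoff = Inf) {
  r2 <- cross_dist2(xyz_a, xyz_b)
  if (any(r2 == 0)) stop("zero interatomic distance (clash singularity)")
  mask <- r2 < cutoff^2
  if (!any(mask)) return(0)
  r2m <- r2[mask]
  Bm <- if (length(B) == 1) B else B[mask]
  Cm <- if (length(C) == 1) C else C[mask]
  Qm <- tcrossprod(qa, qb)[mask]
  sum(Bm / r2m^4 - Cm / r2m^3 + Qm / (15 * r2m))
}

#' @rdname energy_maxdo_raw
#' @export
energy_iattract_raw <- function(xyz_a, xyz_b, sigma, qa, qb, cutoff = Inf) {
  r2 <- cross_dist2(xyz_a, xyz_b)
  if (any(r2 == 0)) stop("zero interatomic distance (clash singularity)")
  mask <- r2 < cutoff^2
  if (!any(mask)) return(0)
  r2m <- r2[mask]
  Sm <- if (length(sigma) == 1) sigma else sigma[mask]
  Qm <- tcrossprod(qa, qb)[mask]
  s6 <- (Sm^2 / r2m)^3
  sum(s6^2 - s6 + Qm / (10 * sqrt(r2m)))
}

cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
}

# Precomputed coefficient matrices for one receptor/ligand pair.
pair_context <- function(receptor, ligand) {
  xa <- cg_coords(receptor); xb <- cg_coords(ligand)
  sa <- receptor$beads$sigma; sb <- ligand$beads$sigma
  ea <- receptor$beads$eps; eb <- ligand$beads$eps
  sig <- outer(sa, sb, `+`) / 2
  eps <- sqrt(outer(ea, eb))
  list(
    xyz_r = xa, xyz_l0 = xb,
    B = 3 * eps * sig^8, C = 4 * eps * sig^6, sigma = sig,
    qa = receptor$beads$q, qb = ligand$beads$q,
    com_l = colMeans(xb)
  )
}

ctx_energy <- function(ctx, tf, energy = c("maxdo", "iattract"), cutoff = 12) {
  energy <- match.arg(energy)
  if (is.null(cutoff)) cutoff <- Inf
  xb <- apply_transform(ctx$xyz_l0, tf)
  if (energy == "maxdo") {
    energy_maxdo_raw(ctx$xyz_r, xb, ctx$B, ctx$C, ctx$qa, ctx$qb, cutoff)
  } else {
    energy_iattract_raw(ctx$xyz_r, xb, ctx$sigma, ctx$qa, ctx$qb, cutoff)
  }
}

#' Docking run settings
#'
#' @param protocol `"surface-restrained"` (ligand centre of mass held on the
#'   receptor-COM ray during minimisation; ordered pairs are independent) or
#'   `"free"` (all six rigid degrees of freedom released; pairs mirrored).
#' @param n_positions Start positions covering the receptor surface.
#' @param n_rotations Orientations per position (rotations of the gamma
#'   Euler angle about the COM-COM axis).
#' @param cutoff Energy cutoff (\eqn{\mathrm{\AA}}).
#' @param seed Mandatory integer seed; all stochastic sampling derives from it.
#' @param energy Energy function minimised, `"maxdo"` or `"iattract"`.
#' @param offset Initial gap added between molecular surfaces (\eqn{\mathrm{\AA}}).
#' @param max_sweeps Coordinate-descent sweep budget per pose.
#' @param tol Energy convergence tolerance.
#' @return A `dock_settings` list.
#' @export
dock_settings <- function(protocol = c("surface-restrained", "free"),
                          n_positions = 64, n_rotations = 12, cutoff = 12,
                          seed = 1, energy = "maxdo", offset = 1,
                          max_sweeps = 30, tol = 1e-4) {
  protocol <- match.arg(protocol)
  stopifnot(n_positions >= 1, n_rotations >= 1, is.numeric(seed))
  structure(list(protocol = protocol, n_positions = n_positions,
                 n_rotations = n_rotations, cutoff = cutoff, seed = as.integer(seed),
                 energy = energy, offset = offset, max_sweeps = max_sweeps, tol = tol),
            class = "dock_settings")
}

#' Generate rigid-body start poses on the receptor surface
#'
#' Start positions are quasi-uniform (golden-spiral) directions from the
#' receptor centre of mass, pushed outward until the ligand sits just beyond
#' the receptor surface; for each position, `n_rotations` orientations are
#' produced by rotating the gamma Euler angle about the receptor-COM to
#' ligand-COM axis. With the free protocol a `candidate_mask` (per-residue
#' logical on the receptor) restricts positions to directions whose nearest
#' surface residue belongs to the mask.
#'
#' @param receptor,ligand `cg_protein` objects.
#' @param protocol See [dock_settings()].
#' @param n_positions,n_rotations Sampling density.
#' @param offset Surface gap (\eqn{\mathrm{\AA}}).
#' @param candidate_mask Optional per-residue logical mask on the receptor.
#' @return List of `rigid_transform` objects (ligand frames), with the start
#'   direction stored in attribute `"direction"`.
#' @export
generate_start_poses <- function(receptor, ligand,
                                 protocol = c("surface-restrained", "free"),
                                 n_positions = 64, n_rotations = 12,
                                 offset = 1, candidate_mask = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(n_positions >= 1, n_rotations >= 1)
  xr <- cg_coords(receptor)
  com_r <- colMeans(xr)
  cen <- sweep(xr, 2, com_r)
  if (nrow(xr) >= 3 && svd(cen)$d[2] < 1e-8) stop("degenerate receptor geometry (collinear pseudoatoms)")
  xl <- cg_coords(ligand)
  com_l <- colMeans(xl)
  lig_radius <- sqrt(max(rowSums(sweep(xl, 2, com_l)^2)))
  dirs <- sphere_points(n_positions)
  if (!is.null(candidate_mask)) {
    ca <- ca_coords(receptor)
    keep <- vapply(seq_len(nrow(dirs)), function(i) {
      ext <- max(cen %*% dirs[i, ])
      p <- com_r + dirs[i, ] * ext
      nearest <- which.min(rowSums(sweep(ca, 2, p)^2))
      isTRUE(candidate_mask[nearest])
    }, logical(1))
    dirs <- dirs[keep, , drop = FALSE]
    if (!nrow(dirs)) stop("candidate mask excludes every start position")
  }
  gammas <- 2 * pi * (seq_len(n_rotations) - 1) / n_rotations
  poses <- list()
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    ext <- max(cen %*% u)
    pos <- com_r + u * (ext + lig_radius + offset)
    base <- rotation_between(c(0, 0, 1), -u)
    for (g in gammas) {
      rot <- rotation_about_axis(u, g) %*% base
      tf <- rigid_transform(rot, pos - as.numeric(rot %*% com_l))
      attr(tf, "direction") <- u
      poses[[length(poses) + 1]] <- tf
    }
  }
  poses
}

#' Locally minimise a docking pose
#'
#' Derivative-free coordinate descent over the rigid degrees of freedom:
#' with the surface-restrained protocol the ligand centre of mass moves only
#' along the receptor-COM ray (1 translational + 3 rotational DOF); with the
#' free protocol all 6 DOF are released. Step sizes shrink geometrically
#' when a sweep brings no improvement; the returned energy never exceeds the
#' start energy and the result is deterministic given the start pose.
#'
#' @param receptor,ligand `cg_protein` objects.
#' @param start `rigid_transform` start pose.
#' @param energy `"maxdo"` or `"iattract"`.
#' @param protocol See [dock_settings()].
#' @param cutoff Energy cutoff.
#' @param step_trans,step_rot Initial step sizes (\eqn{\mathrm{\AA}}, radians).
#' @param tol Convergence tolerance on the energy.
#' @param max_sweeps Sweep budget.
#' @return List with elements `transform` and `energy` (`NULL` transform and
#'   a warning if the energy went non-finite).
#' @export
minimize_pose <- function(receptor, ligand, start,
                          energy = c("maxdo", "iattract"),
                          protocol = c("surface-restrained", "free"),
                          cutoff = 12, step_trans = 1, step_rot = 0.25,
                          tol = 1e-4, max_sweeps = 30) {
  energy <- match.arg(energy)
  protocol <- match.arg(protocol)
  ctx <- pair_context(receptor, ligand)
  com_r <- colMeans(ctx$xyz_r)
  e <- ctx_energy(ctx, start, energy, cutoff)
  if (!is.finite(e)) {
    warning("non-finite energy at start pose; pose discarded")
    return(list(transform = NULL, energy = NA_real_))
  }
  cur <- start
  axes <- diag(3)
  st <- step_trans; sr <- step_rot
  for (sweep_i in seq_len(max_sweeps)) {
    improved <- FALSE
    e_before <- e
    # translational moves
    com_now <- as.numeric(cur$rotation %*% ctx$com_l) + cur$translation
    trans_dirs <- if (protocol == "surface-restrained") {
      u <- com_now - com_r
      list(u / sqrt(sum(u^2)))
    } else {
      list(axes[1, ], axes[2, ], axes[3, ])
    }
    for (u in trans_dirs) {
      for (s in c(st, -st)) {
        cand <- rigid_transform(cur$rotation, cur$translation + s * u)
        ec <- try_energy(ctx, cand, energy, cutoff)
        if (is.finite(ec) && ec < e - 1e-12) {
          cur <- cand; e <- ec; improved <- TRUE
        }
      }
    }
    # rotational moves about the current ligand COM
    com_now <- as.numeric(cur$rotation %*% ctx$com_l) + cur$translation
    for (k in 1:3) {
      for (s in c(sr, -sr)) {
        rot_inc <- rotation_about_axis(axes[k, ], s)
        new_rot <- rot_inc %*% cur$rotation
        new_t <- com_now - as.numeric(new_rot %*% ctx$com_l)
        cand <- rigid_transform(new_rot, new_t)
        ec <- try_energy(ctx, cand, energy, cutoff)
        if (is.finite(ec) && ec < e - 1e-12) {
          cur <- cand; e <- ec; improved <- TRUE
        }
      }
    }
    if (!improved) {
      st <- st / 2; sr <- sr / 2
      if (st < 0.02 && sr < 0.005) break
    } else if (e_before - e < tol && st <= 0.02 && sr <= 0.005) {
      break
    }
  }
  list(transform = cur, energy = e)
}

try_energy <- function(ctx, tf, energy, cutoff) {
  tryCatch(ctx_energy(ctx, tf, energy, cutoff), error = function(e) Inf)
}

#' Complete cross-docking of a protein set
#'
#' Docks every protein against every protein in the set, including itself.
#' With the surface-restrained protocol all \eqn{N^2} ordered pairs are
#' docked independently; with the free protocol the \eqn{N(N+1)/2}
#' unordered pairs are docked once and mirrored. Per-pose failures are
#' logged as warnings, never fatal for the run.
#'
#' @param proteins Named list of `cg_protein` objects (names are protein ids;
#'   unnamed lists use each protein's own `protein_id`).
#' @param settings A [dock_settings()] object; its seed drives all sampling.
#' @return A `conformation_store`: list with a `poses` tibble
#'   (`receptor_id`, `ligand_id`, `pose_id`, `transform` list-column,
#'   `e_maxdo`, optionally more score columns), the protein list, the
#'   protocol tag, the settings and the seed.
#' @export
cross_dock <- function(proteins, settings = dock_settings()) {
  proteins <- name_proteins(proteins)
  ids <- names(proteins)
  pairs <- if (settings$protocol == "surface-restrained") {
    expand.grid(receptor_id = ids, ligand_id = ids, stringsAsFactors = FALSE)
  } else {
    idx <- which(upper.tri(matrix(0, length(ids), length(ids)), diag = TRUE), arr.ind = TRUE)
    data.frame(receptor_id = ids[idx[, 1]], ligand_id = ids[idx[, 2]], stringsAsFactors = FALSE)
  }
  rows <- withr::with_seed(settings$seed, {
    lapply(seq_len(nrow(pairs)), function(k) {
      rid <- pairs$receptor_id[k]; lid <- pairs$ligand_id[k]
      dock_pair(proteins[[rid]], proteins[[lid]], rid, lid, settings)
    })
  })
  poses <- dplyr::bind_rows(rows)
  if (settings$protocol == "free") poses <- mirror_poses(poses)
  new_conformation_store(poses, proteins, settings)
}

dock_pair <- function(receptor, ligand, rid, lid, settings) {
  starts <- generate_start_poses(receptor, ligand, settings$protocol,
                                 settings$n_positions, settings$n_rotations,
                                 offset = settings$offset)
  res <- lapply(starts, function(s) {
    minimize_pose(receptor, ligand, s, settings$energy, settings$protocol,
                  cutoff = settings$cutoff, tol = settings$tol,
                  max_sweeps = settings$max_sweeps)
  })
  keep <- vapply(res, function(r) !is.null(r$transform) && is.finite(r$energy), logical(1))
  res <- res[keep]
  if (!length(res)) return(NULL)
  tibble::tibble(
    receptor_id = rid, ligand_id = lid,
    pose_id = seq_along(res),
    transform = lapply(res, `[[`, "transform"),
    e_maxdo = vapply(res, `[[`, numeric(1), "energy")
  )
}

mirror_poses <- function(poses) {
  rev_rows <- poses[poses$receptor_id != poses$ligand_id, , drop = FALSE]
  if (nrow(rev_rows)) {
    rev_rows <- dplyr::mutate(rev_rows,
      transform = lapply(.data$transform, invert_transform))
    tmp <- rev_rows$receptor_id
    rev_rows$receptor_id <- rev_rows$ligand_id
    rev_rows$ligand_id <- tmp
    if ("di_receptor" %in% names(rev_rows)) {
      di <- rev_rows$di_receptor
      rev_rows$di_receptor <- rev_rows$di_ligand
      rev_rows$di_ligand <- di
    }
  }
  dplyr::bind_rows(poses, rev_rows)
}

name_proteins <- function(proteins) {
  if (inherits(proteins, "cg_protein")) proteins <- list(proteins)
  if (is.null(names(proteins)) || any(names(proteins) == "")) {
    names(proteins) <- vapply(proteins, `[[`, character(1), "protein_id")
  }
  proteins
}

new_conformation_store <- function(poses, proteins, settings) {
  if (nrow(poses)) {
    dup <- poses |>
      dplyr::count(.data$receptor_id, .data$ligand_id, .data$pose_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) stop("duplicate pose ids within a pair")
  }
  structure(list(poses = poses, proteins = proteins,
                 protocol = settings$protocol, settings = settings,
                 seed = settings$seed),
            class = "conformation_store")
}

#' @export
print.conformation_store <- function(x, ...) {
  np <- if (nrow(x$poses)) nrow(dplyr::distinct(x$poses, .data$receptor_id, .data$ligand_id)) else 0
  cat("<conformation_store> ", length(x$proteins), " proteins, ", np,
      " ordered pairs, ", nrow(x$poses), " poses (", x$protocol, ", seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a conformation store into its pose table
#' @param x A `conformation_store`.
#' @param ... Unused.
#' @return The `poses` tibble.
#' @exportS3Method
tidy.conformation_store <- function(x, ...) x$poses

#' Annotate a conformation store with docked interfaces
#'
#' For every pose, finds the residues of the receptor and of the transformed
#' ligand closer than `d` \eqn{\mathrm{\AA}} (pseudoatom distances, strict
#' inequality) and stores them as `di_receptor` / `di_ligand` list-columns
#' of 0-based residue indices.
#'
#' @param store A `conformation_store`.
#' @param d Distance threshold in \eqn{\mathrm{\AA}} (4.5, 5 or 6 in typical use).
#' @return The store with interface columns added and attribute `d` recorded.
#' @export
docked_interfaces <- function(store, d = 5) {
  stopifnot(inherits(store, "conformation_store"), d > 0)
  poses <- store$poses
  di_r <- vector("list", nrow(poses))
  di_l <- vector("list", nrow(poses))
  for (k in seq_len(nrow(poses))) {
    rec <- store$proteins[[poses$receptor_id[k]]]
    lig <- store$proteins[[poses$ligand_id[k]]]
    xl <- apply_transform(cg_coords(lig), poses$transform[[k]])
    di <- detect_interface_coords(cg_coords(rec), rec$beads$res_idx,
                                  xl, lig$beads$res_idx, d)
    di_r[[k]] <- di$a
    di_l[[k]] <- di$b
  }
  poses$di_receptor <- di_r
  poses$di_ligand <- di_l
  store$poses <- poses
  store$d <- d
  store
}

#' Attach external per-conformation scores to a store
#'
#' Ingests a score table (e.g. an assembly-stability score computed by an
#' external program) keyed by pair and pose id.
#'
#' @param store A `conformation_store`.
#' @param scores Data frame with columns `receptor_id`, `ligand_id`,
#'   `pose_id` and `score`.
#' @param column Name of the column added (default `"e_external"`).
#' @return The store with the score column joined in.
#' @export
add_external_energy <- function(store, scores, column = "e_external") {
  stopifnot(inherits(store, "conformation_store"),
            all(c("receptor_id", "ligand_id", "pose_id", "score") %in% names(scores)))
  scores <- tibble::as_tibble(scores)
  names(scores)[names(scores) == "score"] <- column
  store$poses <- dplyr::left_join(store$poses, scores,
                                  by = c("receptor_id", "ligand_id", "pose_id"))
  store
}

#' Write / read a conformation store as tab-separated text
#'
#' The pose table is flattened to one row per pose with the twelve transform
#' numbers (`r11`..`r33` row-major, `t1`..`t3`) and any docked-interface
#' sets as comma-separated residue indices. Protein models are written
#' alongside with [write_cg_table()].
#'
#' @param store A `conformation_store`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  poses <- store$poses
  tf <- t(vapply(poses$transform, function(x) c(t(x$rotation), x$translation), numeric(12)))
  colnames(tf) <- c(paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33)), paste0("t", 1:3))
  flat <- dplyr::bind_cols(poses[setdiff(names(poses), c("transform", "di_receptor", "di_ligand"))],
                           tibble::as_tibble(tf))
  for (col in c("di_receptor", "di_ligand")) {
    if (col %in% names(poses)) {
      flat[[col]] <- vapply(poses[[col]], paste, character(1), collapse = ",")
    }
  }
  utils::write.table(flat, file.path(dir, "poses.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(protocol = store$protocol, seed = store$seed, d = store$d,
               settings = store$settings[setdiff(names(store$settings), "protocol")])
  jsonlite::write_json(meta, file.path(dir, "store.json"), auto_unbox = TRUE, null = "null")
  for (id in names(store$proteins)) {
    write_cg_table(store$proteins[[id]], file.path(dir, paste0(id, ".cg.tsv")))
  }
  invisible(dir)
}

#' @rdname write_store
#' @export
read_store <- function(dir) {
  flat <- tibble::as_tibble(utils::read.table(file.path(dir, "poses.tsv"), sep = "\t",
                                              header = TRUE, stringsAsFactors = FALSE))
  meta <- jsonlite::read_json(file.path(dir, "store.json"))
  rot_cols <- paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
  tcols <- paste0("t", 1:3)
  transforms <- lapply(seq_len(nrow(flat)), function(i) {
    rigid_transform(matrix(as.numeric(flat[i, rot_cols]), 3, 3, byrow = TRUE),
                    as.numeric(flat[i, tcols]))
  })
  poses <- flat[, setdiff(names(flat), c(rot_cols, tcols)), drop = FALSE]
  poses$transform <- transforms
  for (col in c("di_receptor", "di_ligand")) {
    if (col %in% names(poses)) {
      poses[[col]] <- lapply(strsplit(as.character(poses[[col]]), ","), function(v) {
        as.integer(v[v != "" & !is.na(v)])
      })
    }
  }
  cg_files <- list.files(dir, pattern = "\\.cg\\.tsv$", full.names = TRUE)
  proteins <- lapply(cg_files, read_cg_table)
  names(proteins) <- sub("\\.cg$", "", vapply(proteins, `[[`, character(1), "protein_id"))
  proteins <- lapply(proteins, function(p) { p$protein_id <- sub("\\.cg$", "", p$protein_id); p })
  st <- structure(list(poses = poses, proteins = proteins, protocol = meta$protocol,
                       settings = meta$settings, seed = meta$seed),
                  class = "conformation_store")
  if (!is.null(meta$d)) st$d <- meta$d
  st
}
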