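#' Specification of a synthetic benchmark fixture
#'
#' Defines the seeded toy study conditions used throughout the test suite:
#' quasi-spherical single-bead shell "proteins" carrying designed,
#' charge-complementary interface patches. Cognate pairs carry opposite
#' copies of mutually orthogonal +/- charge codes on their patches, so the
#' bound pose of a cognate pair is strongly favourable while non-cognate
#' patch contacts gain almost nothing from electrostatics.
#'
#' @param seed Integer seed; the same spec reproduces the fixture exactly.
#' @param n_proteins Number of proteins (even; N/2 cognate pairs).
#' @param n_residues Residues (beads) per protein shell.
#' @param patch_size Designed interface size (residues).
#' @param charge Charge-complementarity magnitude (elementary units) on the
#'   patch beads.
#' @param bump Amplitude (\eqn{\mathrm{\AA}}) of the pair-specific
#'   bump/recess relief embossed on the patches (the geometric lock).
#' @param bead_sigma,bead_eps LJ scales of the beads (\eqn{\mathrm{\AA}},
#'   energy units).
#' @param spacing Target nearest-neighbour bead spacing (\eqn{\mathrm{\AA}});
#'   keeps the 5 \eqn{\mathrm{\AA}} surface graph connected.
#' @param jitter Gaussian positional jitter per bead (\eqn{\mathrm{\AA}}).
#' @param noise_energy Gaussian noise added to planted energies by
#'   [make_scored_store()].
#' @param classes Class labels assigned round-robin to cognate pairs.
#' @param sticky Plant one indiscriminately binding protein (the first) in
#'   [make_scored_store()].
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_proteins = 8, n_residues = 42,
                         patch_size = 8, charge = 24, bump = 1.2,
                         bead_sigma = 4, bead_eps = 0.3, spacing = 4.2,
                         jitter = 0.15, noise_energy = 0,
                         classes = c("alpha", "beta"), sticky = FALSE) {
  stopifnot(patch_size < n_residues, n_residues >= 12)
  structure(list(seed = as.integer(seed), n_proteins = n_proteins,
                 n_residues = n_residues, patch_size = patch_size,
                 charge = charge, bump = bump,
                 bead_sigma = bead_sigma, bead_eps = bead_eps,
                 spacing = spacing, jitter = jitter, noise_energy = noise_energy,
                 classes = classes, sticky = sticky),
            class = "fixture_spec")
}

# shell of single-bead pseudo-residues on a sphere; patch = top-z cap
toy_shell <- function(id, spec, charges = NULL) {
  n <- spec$n_residues
  R <- spec$spacing * sqrt(sqrt(3) / (8 * pi) * n)
  xyz <- sphere_points(n) * R
  if (spec$jitter > 0) xyz <- xyz + matrix(stats::rnorm(3 * n, 0, spec$jitter), n, 3)
  q <- if (is.null(charges)) rep(0, n) else charges
  beads <- tibble::tibble(res_idx = seq_len(n) - 1L, role = "CA",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          q = q, type = "BEAD",
                          sigma = spec$bead_sigma, eps = spec$bead_eps)
  cg_protein(id, beads)
}

toy_patch <- function(protein, patch_size) {
  z <- cg_coords(protein)[, 3]
  sort(order(z, decreasing = TRUE)[seq_len(patch_size)] - 1L)
}

# mutually orthogonal, zero-sum +/-1 codes (Sylvester-Hadamard rows when the
# length is a power of two, otherwise seeded balanced random codes)
orthogonal_codes <- function(n_codes, len) {
  is_pow2 <- len > 1 && bitwAnd(len, len - 1L) == 0
  if (is_pow2 && n_codes <= len - 1) {
    h <- matrix(1, 1, 1)
    while (ncol(h) < len) h <- rbind(cbind(h, h), cbind(h, -h))
    return(h[1 + seq_len(n_codes), , drop = FALSE])
  }
  codes <- matrix(0, n_codes, len)
  half <- floor(len / 2)
  for (k in seq_len(n_codes)) {
    v <- rep(c(1, -1), c(half, len - half))
    codes[k, ] <- sample(v)
  }
  codes
}

#' Build one cognate toy complex
#'
#' Two shell proteins with geometrically matched polar patches carrying
#' opposite charge codes, posed in contact (patch against patch at the LJ
#' contact distance). At generation, the bound pose is asserted to score
#' lower (8-6 energy, no cutoff) than 95% of random surface poses.
#'
#' @param spec A [fixture_spec()].
#' @param ids Identifiers of the two proteins.
#' @param code Optional +/-1 charge code of length `patch_size`.
#' @param assert Run the generation-time energy check (default TRUE).
#' @return List with `a`, `b` (`cg_protein`), `bound` (`rigid_transform`
#'   for b), `interfaces` (designed `dm_interface` pair) and `spec`.
#' @export
make_toy_complex <- function(spec = fixture_spec(), ids = c("A", "B"),
                             code = NULL, assert = TRUE) {
  withr::with_seed(spec$seed, {
    pats <- orthogonal_codes(2, spec$patch_size)
    if (is.null(code)) code <- pats[1, ]
    cx <- build_toy_pair(spec, ids, code, pats[2, ])
    if (assert) {
      e_bound <- pair_energy_maxdo(cx$a, cx$b, cx$bound, cutoff = Inf)
      e_rand <- random_contact_energies(cx$a, cx$b, 100)
      if (!(e_bound < stats::quantile(e_rand, 0.05))) {
        stop("infeasible fixture geometry: bound pose not in the lowest 5% of random poses")
      }
    }
    cx
  })
}

build_toy_pair <- function(spec, ids, code, relief = NULL) {
  # the relief pattern is kept orthogonal to the charge code so that the
  # bump/recess displacements do not systematically push like charges together
  if (is.null(relief)) relief <- orthogonal_codes(2, spec$patch_size)[2, ]
  a <- toy_shell(ids[1], spec)
  patch_a <- toy_patch(a, spec$patch_size)
  # flatten the cap into a planar patch at the cap-edge height, then emboss
  # the pair's +/- code as a bump/recess relief: the patch can only mate
  # over its full extent with the complementary relief of its cognate
  zc <- min(a$beads$z[patch_a + 1L])
  a$beads$z[patch_a + 1L] <- zc + spec$bump * relief
  qa <- rep(0, spec$n_residues)
  qa[patch_a + 1L] <- spec$charge * code
  a$beads$q <- qa
  b <- toy_shell(ids[2], spec)
  patch_b <- toy_patch(b, spec$patch_size)
  # b's patch is the mirror image (y -> -y) of a's patch with the
  # complementary relief, so the half-turn of the bound pose brings every
  # matched bead pair face to face at the contact distance
  b$beads$x[patch_b + 1L] <- a$beads$x[patch_a + 1L] +
    stats::rnorm(spec$patch_size, 0, spec$jitter)
  b$beads$y[patch_b + 1L] <- -a$beads$y[patch_a + 1L] +
    stats::rnorm(spec$patch_size, 0, spec$jitter)
  b$beads$z[patch_b + 1L] <- zc - spec$bump * relief
  qb <- rep(0, spec$n_residues)
  qb[patch_b + 1L] <- -spec$charge * code
  b$beads$q <- qb
  # bound pose: half-turn about x stacks the patches at the contact distance
  rot <- rotation_about_axis(c(1, 0, 0), pi)
  bound <- rigid_transform(rot, c(0, 0, 2 * zc + spec$bead_sigma))
  list(a = a, b = b, bound = bound,
       interfaces = list(a = new_interface(ids[1], patch_a, "experimental", 5),
                         b = new_interface(ids[2], patch_b, "experimental", 5)),
       spec = spec)
}

random_contact_energies <- function(a, b, n) {
  xa <- cg_coords(a); xb <- cg_coords(b)
  com_a <- colMeans(xa); com_b <- colMeans(xb)
  rb <- sqrt(max(rowSums(sweep(xb, 2, com_b)^2)))
  vapply(seq_len(n), function(i) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ext <- max(sweep(xa, 2, com_a) %*% u)
    pos <- com_a + u * (ext + rb)
    rot <- random_rotations(1)[[1]]
    tf <- rigid_transform(rot, pos - as.numeric(rot %*% com_b))
    pair_energy_maxdo(a, b, tf, cutoff = Inf)
  }, numeric(1))
}

#' Build a synthetic cross-docking benchmark set
#'
#' N shell proteins forming N/2 designed cognate pairs with mutually
#' orthogonal charge codes, class labels assigned round-robin to the pairs
#' (both partners of a pair share a class), and the designed patches as
#' ground-truth interfaces.
#'
#' @param spec A [fixture_spec()] (`n_proteins` must be even).
#' @param assert Run the generation-time bound-pose energy check on each pair.
#' @return List with `proteins` (named list), `pairs` (tibble `a`, `b`),
#'   `classes` (named vector), `interfaces` (named list of designed
#'   `dm_interface`), `bound` (named list of bound transforms per pair) and
#'   `spec`.
#' @export
make_benchmark_set <- function(spec = fixture_spec(), assert = TRUE) {
  if (spec$n_proteins %% 2 != 0) stop("n_proteins must be even (N/2 cognate pairs)")
  n_pairs <- spec$n_proteins / 2
  withr::with_seed(spec$seed, {
    codes <- orthogonal_codes(n_pairs + 1, spec$patch_size)
    proteins <- list(); interfaces <- list(); bound <- list()
    pairs <- tibble::tibble(a = character(n_pairs), b = character(n_pairs))
    for (k in seq_len(n_pairs)) {
      ids <- sprintf("p%02d", c(2 * k - 1, 2 * k))
      cx <- build_toy_pair(spec, ids, codes[k, ], codes[k + 1, ])
      if (assert) {
        e_bound <- pair_energy_maxdo(cx$a, cx$b, cx$bound, cutoff = Inf)
        e_rand <- random_contact_energies(cx$a, cx$b, 50)
        if (!(e_bound < stats::quantile(e_rand, 0.05))) {
          stop("infeasible fixture geometry for pair ", k)
        }
      }
      proteins[[ids[1]]] <- cx$a
      proteins[[ids[2]]] <- cx$b
      interfaces[[ids[1]]] <- cx$interfaces$a
      interfaces[[ids[2]]] <- cx$interfaces$b
      bound[[paste(ids, collapse = "-")]] <- cx$bound
      pairs$a[k] <- ids[1]; pairs$b[k] <- ids[2]
    }
    cls <- rep(spec$classes, length.out = n_pairs)
    classes <- stats::setNames(rep(cls, each = 2), names(proteins))
    list(proteins = proteins, pairs = pairs, classes = classes,
         interfaces = interfaces, bound = bound, spec = spec)
  })
}

#' Plant a pre-scored conformation store
#'
#' Bypasses docking: every ordered pair receives `n_conformations` planted
#' conformations with controlled docked interfaces, energies and
#' pair-potential scores, so that pair scoring and evaluation are testable
#' in milliseconds. Cognate pairs get one near-native conformation whose
#' docked interfaces equal the designed patches and whose energy is well
#' below the decoys'; all pairs get random-patch decoy conformations. With
#' `spec$sticky`, the first protein additionally gets a strong planted
#' conformation against every partner (an indiscriminate binder). Energies
#' carry Gaussian noise of sd `spec$noise_energy`; `e_iattract` and
#' `e_external` columns are correlated rescalings of `e_maxdo`.
#'
#' @param spec A [fixture_spec()].
#' @param n_conformations Conformations planted per ordered pair.
#' @param bench Optional pre-built [make_benchmark_set()] output.
#' @return A `conformation_store` with `di_receptor`/`di_ligand`, `e_maxdo`,
#'   `e_iattract`, `e_external` and `pp` columns; the benchmark is attached
#'   as attribute `"benchmark"`.
#' @export
make_scored_store <- function(spec = fixture_spec(), n_conformations = 12,
                              bench = NULL) {
  stopifnot(n_conformations >= 2)
  if (is.null(bench)) bench <- make_benchmark_set(spec, assert = FALSE)
  ids <- names(bench$proteins)
  cognate <- c(paste(bench$pairs$a, bench$pairs$b, sep = "\r"),
               paste(bench$pairs$b, bench$pairs$a, sep = "\r"))
  sticky_id <- if (isTRUE(spec$sticky)) ids[1] else NULL
  rows <- withr::with_seed(spec$seed + 1L, {
    out <- list()
    for (rid in ids) {
      for (lid in ids) {
        n_res_r <- nrow(bench$proteins[[rid]]$residues)
        n_res_l <- nrow(bench$proteins[[lid]]$residues)
        di_r <- lapply(seq_len(n_conformations), function(i) {
          sort(sample.int(n_res_r, spec$patch_size) - 1L)
        })
        di_l <- lapply(seq_len(n_conformations), function(i) {
          sort(sample.int(n_res_l, spec$patch_size) - 1L)
        })
        e <- stats::runif(n_conformations, -2, -0.2)
        pp <- stats::rnorm(n_conformations)
        # every pair has one weak conformation sitting on the designed
        # patches (non-interactors also dock onto binding sites)
        di_r[[2]] <- bench$interfaces[[rid]]$residues
        di_l[[2]] <- bench$interfaces[[lid]]$residues
        e[2] <- stats::runif(1, -1.5, -0.5)
        if (paste(rid, lid, sep = "\r") %in% cognate) {
          di_r[[1]] <- bench$interfaces[[rid]]$residues
          di_l[[1]] <- bench$interfaces[[lid]]$residues
          e[1] <- -10
          pp[1] <- 5
        } else if (!is.null(sticky_id) && (rid == sticky_id || lid == sticky_id) && rid != lid) {
          di_r[[1]] <- bench$interfaces[[rid]]$residues
          di_l[[1]] <- bench$interfaces[[lid]]$residues
          e[1] <- -8
          pp[1] <- 4
        }
        if (spec$noise_energy > 0) e <- e + stats::rnorm(n_conformations, 0, spec$noise_energy)
        out[[length(out) + 1]] <- tibble::tibble(
          receptor_id = rid, ligand_id = lid,
          pose_id = seq_len(n_conformations),
          transform = replicate(n_conformations, rigid_transform(), simplify = FALSE),
          e_maxdo = e,
          e_iattract = 1.1 * e + stats::rnorm(n_conformations, 0, 0.01),
          e_external = 0.9 * e + stats::rnorm(n_conformations, 0, 0.01),
          pp = pp,
          di_receptor = di_r, di_ligand = di_l
        )
      }
    }
    out
  })
  settings <- dock_settings(seed = spec$seed)
  store <- new_conformation_store(dplyr::bind_rows(rows), bench$proteins, settings)
  store$d <- 5
  attr(store, "benchmark") <- bench
  store
}

#' Toy surface with a designed interface of exact size
#'
#' A single shell protein, its 5 \eqn{\mathrm{\AA}} surface graph and a
#' polar-cap interface of exactly `interface_size` residues — the fixture
#' used to exercise interface shifting.
#'
#' @param interface_size Residues in the designed interface.
#' @param n_residues Shell size.
#' @param seed Seed.
#' @return List with `protein`, `graph`, `interface`.
#' @export
make_toy_surface <- function(interface_size = 20, n_residues = 80, seed = 1) {
  spec <- fixture_spec(seed = seed, n_residues = n_residues,
                       patch_size = interface_size)
  protein <- withr::with_seed(seed, toy_shell("surf", spec))
  graph <- surface_graph(protein, d = 5)
  interface <- new_interface("surf", toy_patch(protein, interface_size), "experimental", 5)
  list(protein = protein, graph = graph, interface = interface)
}

#' Write a toy shell protein as a PDB-like file
#'
#' Beads are written as glycine C\eqn{\alpha} ATOM records so the file can
#' be driven through the atomic loading and coarse-graining path. The file
#' is synthetic, not a physical protein.
#'
#' @param protein A single-bead-per-residue `cg_protein`.
#' @param path Output path.
#' @export
write_toy_pdb <- function(protein, path) {
  beads <- protein$beads[protein$beads$role == "CA", , drop = FALSE]
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(beads)), beads$res_idx + 1L, beads$x, beads$y, beads$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a synthetic benchmark to the pipeline's file layout
#'
#' Emits per-protein PDB-like files, a manifest (protein id, path, class),
#' the cognate pair list and the designed interfaces.
#'
#' @param bench Output of [make_benchmark_set()].
#' @param dir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble::tibble(
    protein_id = names(bench$proteins),
    path = file.path(dir, paste0(names(bench$proteins), ".pdb")),
    class = unname(bench$classes[names(bench$proteins)])
  )
  for (i in seq_len(nrow(manifest))) {
    write_toy_pdb(bench$proteins[[manifest$protein_id[i]]], manifest$path[i])
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bench$pairs, file.path(dir, "cognate_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_interface_table(bench$interfaces, file.path(dir, "interfaces.tsv"),
                        proteins = bench$proteins)
  invisible(manifest)
}
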