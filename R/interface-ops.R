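#' Interface record
#'
#' A set of residues on one protein, with provenance.
#'
#' @param protein_id Protein identifier.
#' @param residues Integer vector of 0-based internal residue indices.
#' @param provenance `"experimental"`, `"predicted"` or `"decoy"`.
#' @param d Distance threshold (\eqn{\mathrm{\AA}}) used to define the
#'   interface, when applicable.
#' @return A `dm_interface` object.
#' @export
new_interface <- function(protein_id, residues,
                          provenance = c("experimental", "predicted", "decoy"),
                          d = NA_real_) {
  provenance <- match.arg(provenance)
  residues <- sort(unique(as.integer(residues)))
  if (!length(residues) && provenance != "decoy") {
    warning("empty ", provenance, " interface for ", protein_id)
  }
  structure(list(protein_id = protein_id, residues = residues,
                 provenance = provenance, d = d),
            class = "dm_interface")
}

#' @export
print.dm_interface <- function(x, ...) {
  cat("<interface> ", x$protein_id, " (", x$provenance, "): ",
      length(x$residues), " residues\n", sep = "")
  invisible(x)
}

iface_residues <- function(x) if (inherits(x, "dm_interface")) x$residues else sort(unique(as.integer(x)))

#' Detect the interface between two structures
#'
#' A residue of one partner belongs to the interface iff any of its atoms
#' (heavy atoms for atomic structures, pseudoatoms for coarse-grained ones)
#' lies strictly closer than `d` \eqn{\mathrm{\AA}} to any atom of the other
#' partner, and symmetrically.
#'
#' @param a,b `atomic_protein` or `cg_protein` objects, or coordinate
#'   matrices (then `res_idx_a`/`res_idx_b` give the per-atom residue index,
#'   default one residue per row).
#' @param d Distance threshold (\eqn{\mathrm{\AA}}), strict inequality.
#' @param res_idx_a,res_idx_b Per-atom 0-based residue indices for matrix input.
#' @return List with sorted 0-based residue index vectors `a` and `b`.
#' @export
detect_interface <- function(a, b, d = 5, res_idx_a = NULL, res_idx_b = NULL) {
  stopifnot(d > 0)
  ca <- protein_atoms(a, res_idx_a)
  cb <- protein_atoms(b, res_idx_b)
  detect_interface_coords(ca$xyz, ca$res_idx, cb$xyz, cb$res_idx, d)
}

protein_atoms <- function(x, res_idx = NULL) {
  if (inherits(x, "atomic_protein")) {
    list(xyz = as.matrix(x$atoms[, c("x", "y", "z")]), res_idx = x$atoms$res_idx)
  } else if (inherits(x, "cg_protein")) {
    list(xyz = cg_coords(x), res_idx = x$beads$res_idx)
  } else {
    xyz <- as.matrix(x)
    if (is.null(res_idx)) res_idx <- seq_len(nrow(xyz)) - 1L
    list(xyz = xyz, res_idx = as.integer(res_idx))
  }
}

detect_interface_coords <- function(xyz_a, res_a, xyz_b, res_b, d) {
  if (!nrow(xyz_a) || !nrow(xyz_b)) stop("empty protein in interface detection")
  d2 <- cross_dist2(xyz_a, xyz_b)
  hit <- d2 < d^2
  list(a = sort(unique(res_a[rowSums(hit) > 0])),
       b = sort(unique(res_b[colSums(hit) > 0])))
}

#' Experimental interface of a bound complex
#'
#' Runs [detect_interface()] on the bound coordinates with a 5 \eqn{\mathrm{\AA}}
#' threshold and wraps both sides as experimental interfaces.
#'
#' @param a,b The two partners of the complex (`atomic_protein` or `cg_protein`).
#' @param d Distance threshold, default 5 \eqn{\mathrm{\AA}}.
#' @param on_empty `"warn"` returns empty interfaces with a warning,
#'   `"error"` aborts, when the partners make no contact.
#' @return List of two `dm_interface` objects (`a`, `b`).
#' @export
experimental_interface <- function(a, b, d = 5, on_empty = c("warn", "error")) {
  on_empty <- match.arg(on_empty)
  di <- detect_interface(a, b, d)
  if (!length(di$a) && !length(di$b)) {
    if (on_empty == "error") stop("no contact between the two partners at d = ", d)
    warning("no contact between the two partners at d = ", d)
  }
  id_a <- if (is.list(a) && !is.null(a$protein_id)) a$protein_id else "A"
  id_b <- if (is.list(b) && !is.null(b$protein_id)) b$protein_id else "B"
  list(a = suppressWarnings(new_interface(id_a, di$a, "experimental", d)),
       b = suppressWarnings(new_interface(id_b, di$b, "experimental", d)))
}

#' Surface adjacency graph of a protein
#'
#' Nodes are surface residues; two residues are adjacent iff their reference
#' atoms lie closer than `d` \eqn{\mathrm{\AA}} (no self-edges). By default
#' adjacency uses C\eqn{\alpha} (or bead) positions; `atoms = "all"` uses
#' any-heavy-atom distances.
#'
#' @param protein `atomic_protein` or `cg_protein`.
#' @param surface Per-residue logical surface mask; default marks every
#'   residue as surface (appropriate for convex toy shells), use
#'   [surface_residues()] for real structures.
#' @param d Adjacency distance, default 5 \eqn{\mathrm{\AA}}.
#' @param atoms `"ca"` or `"all"`.
#' @return A `surface_graph`: list with `protein_id`, `surface` mask,
#'   `coords` (per-residue C\eqn{\alpha} positions), and `neighbors`
#'   (adjacency list over residue indices, names are indices as characters).
#' @export
surface_graph <- function(protein, surface = NULL, d = 5, atoms = c("ca", "all")) {
  atoms <- match.arg(atoms)
  n_res <- nrow(protein$residues)
  if (is.null(surface)) surface <- rep(TRUE, n_res)
  stopifnot(length(surface) == n_res)
  ca <- residue_ca(protein)
  if (atoms == "ca") {
    d2 <- cross_dist2(ca, ca)
    adj <- d2 < d^2
  } else {
    pa <- protein_atoms(protein)
    hit2 <- cross_dist2(pa$xyz, pa$xyz) < d^2
    adj <- matrix(FALSE, n_res, n_res)
    for (i in seq_len(n_res)) {
      sel <- pa$res_idx == (i - 1L)
      adj[i, ] <- vapply(seq_len(n_res), function(j) {
        any(hit2[sel, pa$res_idx == (j - 1L)])
      }, logical(1))
    }
  }
  diag(adj) <- FALSE
  adj[!surface, ] <- FALSE
  adj[, !surface] <- FALSE
  neighbors <- lapply(seq_len(n_res), function(i) which(adj[i, ]) - 1L)
  names(neighbors) <- as.character(seq_len(n_res) - 1L)
  structure(list(protein_id = protein$protein_id, surface = surface,
                 coords = ca, neighbors = neighbors, d = d),
            class = "surface_graph")
}

residue_ca <- function(protein) {
  if (inherits(protein, "cg_protein")) return(ca_coords(protein))
  at <- protein$atoms
  ca <- at[at$elety == "CA", , drop = FALSE]
  n_res <- nrow(protein$residues)
  out <- matrix(NA_real_, n_res, 3)
  out[ca$res_idx + 1L, ] <- as.matrix(ca[, c("x", "y", "z")])
  # residues lacking CA: centroid
  miss <- which(is.na(out[, 1]))
  for (i in miss) {
    sel <- at$res_idx == (i - 1L)
    out[i, ] <- colMeans(as.matrix(at[sel, c("x", "y", "z")]))
  }
  out
}

graph_neighbors <- function(graph, res) graph$neighbors[[as.character(res)]]

# connected components of a residue set on the surface graph
graph_components <- function(graph, residues) {
  residues <- sort(unique(as.integer(residues)))
  comp <- list()
  left <- residues
  while (length(left)) {
    queue <- left[1]
    seen <- queue
    left <- left[-1]
    while (length(queue)) {
      nb <- unique(unlist(lapply(queue, graph_neighbors, graph = graph)))
      nb <- intersect(nb, left)
      seen <- c(seen, nb)
      left <- setdiff(left, nb)
      queue <- nb
    }
    comp[[length(comp) + 1]] <- sort(seen)
  }
  comp
}

round_half_up <- function(x) floor(x + 0.5)

#' Shift an interface into a same-size decoy
#'
#' Performs `m = round(fraction * N)` border swaps (half-up rounding): at
#' each iteration a border interface residue \eqn{r_s} (one with a surface
#' neighbour outside the interface) is removed, the interface residue
#' farthest from it (C\eqn{\alpha} distance, ties to the lowest index) is
#' located, and one of that residue's surface neighbours outside the
#' interface, \eqn{r_n}, is added. The residue removed at one iteration is
#' not eligible as \eqn{r_s} at the next. Swaps preferentially move a
#' residue of the source interface out and a residue never in the source in,
#' so that a decoy at shift level \eqn{m/N} has F1 \eqn{=(N-m)/N} against
#' its source; when no such candidate exists (deep shift levels) any
#' eligible residue is used.
#'
#' @param interface A `dm_interface` (or integer residue vector).
#' @param graph [surface_graph()] of the same protein.
#' @param fraction Shift level in (0, 1].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A `dm_interface` with provenance `"decoy"`, same cardinality as
#'   the source, with the per-iteration log in attribute `"log"`.
#' @export
shift_decoy <- function(interface, graph, fraction, seed = NULL) {
  src <- iface_residues(interface)
  N <- length(src)
  m <- round_half_up(fraction * N)
  stopifnot(fraction > 0, fraction <= 1, N > 0)
  pid <- if (inherits(interface, "dm_interface")) interface$protein_id else graph$protein_id
  run <- function() {
    cur <- src
    prev_rs <- NA_integer_
    log <- vector("list", m)
    if (m > 0) {
      for (it in seq_len(m)) {
        border <- cur[vapply(cur, function(r) {
          nb <- graph_neighbors(graph, r)
          length(setdiff(nb, cur)) > 0
        }, logical(1))]
        border <- setdiff(border, prev_rs)
        if (!length(border)) {
          stop("shift_decoy stuck at iteration ", it, ": no eligible border residue")
        }
        clean_rs <- intersect(border, src)
        pool_rs <- if (length(clean_rs)) clean_rs else border
        rs <- pool_rs[sample.int(length(pool_rs), 1)]
        others <- setdiff(cur, rs)
        d2 <- rowSums(sweep(graph$coords[others + 1L, , drop = FALSE], 2,
                            graph$coords[rs + 1L, ], `-`)^2)
        far <- others[order(-d2, others)][1]
        nbrs <- setdiff(graph_neighbors(graph, far), cur)
        if (!length(nbrs)) {
          stop("shift_decoy stuck at iteration ", it,
               ": farthest residue ", far, " has no surface neighbour outside the interface")
        }
        clean_rn <- setdiff(nbrs, src)
        pool_rn <- if (length(clean_rn)) clean_rn else nbrs
        rn <- pool_rn[sample.int(length(pool_rn), 1)]
        cur <- sort(c(setdiff(cur, rs), rn))
        prev_rs <- rs
        log[[it]] <- tibble::tibble(iteration = it, removed = rs, farthest = far, added = rn)
      }
    }
    out <- new_interface(pid, cur, "decoy", graph$d)
    attr(out, "log") <- dplyr::bind_rows(log)
    attr(out, "source") <- src
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Series of shifted decoys over increasing shift levels
#'
#' Generates `n_per_level` decoys at each shift level (10%, 20%, ...,
#' 100% by default), in order: the first `n_per_level` decoys are at the
#' first level, the next `n_per_level` at the second, and so on.
#'
#' @inheritParams shift_decoy
#' @param levels Shift fractions, default `seq(0.1, 1, by = 0.1)`.
#' @param n_per_level Decoys per level, default 10.
#' @param seed Seed for the whole series.
#' @return List of `length(levels) * n_per_level` decoy interfaces, with the
#'   level of each recorded in attribute `"level"`.
#' @export
decoy_series <- function(interface, graph, seed = 1,
                         levels = seq(0.1, 1, by = 0.1), n_per_level = 10) {
  withr::with_seed(seed, {
    out <- list()
    for (lev in levels) {
      for (r in seq_len(n_per_level)) {
        dec <- shift_decoy(interface, graph, lev, seed = NULL)
        attr(dec, "level") <- lev
        out[[length(out) + 1]] <- dec
      }
    }
    out
  })
}

#' Agreement between a predicted and a reference interface
#'
#' @param predicted,reference `dm_interface` objects on the same protein
#'   (or integer residue vectors).
#' @return One-row tibble with `f1`, `sensitivity` (recall against the
#'   reference) and `ppv` (precision of the prediction). An empty predicted
#'   interface yields all zeros with a warning.
#' @export
interface_agreement <- function(predicted, reference) {
  if (inherits(predicted, "dm_interface") && inherits(reference, "dm_interface") &&
      !identical(predicted$protein_id, reference$protein_id)) {
    stop("interfaces belong to different proteins: ",
         predicted$protein_id, " vs ", reference$protein_id)
  }
  p <- iface_residues(predicted)
  r <- iface_residues(reference)
  if (!length(p)) {
    warning("empty predicted interface")
    return(tibble::tibble(f1 = 0, sensitivity = 0, ppv = 0))
  }
  tp <- length(intersect(p, r))
  ppv <- tp / length(p)
  sens <- if (length(r)) tp / length(r) else 0
  f1 <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  tibble::tibble(f1 = f1, sensitivity = sens, ppv = ppv)
}

#' Write / read interfaces as tab-separated residue lists
#'
#' One residue per row: protein id, chain, author residue number, internal
#' 0-based index, provenance.
#'
#' @param interfaces A `dm_interface` or list of them.
#' @param proteins Named list of proteins supplying author numbering
#'   (optional; without it chain/author columns are `NA`).
#' @param path Output path.
#' @export
write_interface_table <- function(interfaces, path, proteins = NULL) {
  if (inherits(interfaces, "dm_interface")) interfaces <- list(interfaces)
  rows <- lapply(interfaces, function(ifc) {
    tab <- tibble::tibble(protein_id = ifc$protein_id, res_idx = ifc$residues,
                          provenance = ifc$provenance)
    pr <- proteins[[ifc$protein_id]]
    if (!is.null(pr)) {
      tab <- dplyr::left_join(tab, pr$residues[, c("res_idx", "chain", "resno")], by = "res_idx")
    } else {
      tab$chain <- NA_character_; tab$resno <- NA_integer_
    }
    tab[, c("protein_id", "chain", "resno", "res_idx", "provenance")]
  })
  utils::write.table(dplyr::bind_rows(rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interface_table
#' @export
read_interface_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  split_tab <- split(tab, tab$protein_id)
  lapply(split_tab, function(tt) {
    suppressWarnings(new_interface(tt$protein_id[1], tt$res_idx, tt$provenance[1]))
  })
}
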