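#' Circular variance of a residue's neighbourhood
#'
#' CV = 1 - ||sum of unit vectors|| / n over unit vectors from the residue's
#' C-alpha to every neighbour C-alpha within `radius`. Low values mark
#' protruding residues whose neighbours concentrate in one direction; values
#' near 1 mark buried, isotropically surrounded residues. Residues with no
#' neighbour get CV = 0 with a warning.
#'
#' @param protein `atomic_protein` or `cg_protein`.
#' @param radius Neighbourhood radius, default 12 \eqn{\mathrm{\AA}}.
#' @return Numeric vector in \[0, 1\] over all residues (in `res_idx` order).
#' @export
circular_variance <- function(protein, radius = 12) {
  stopifnot(radius > 0)
  ca <- residue_ca(protein)
  n <- nrow(ca)
  out <- numeric(n)
  lonely <- FALSE
  for (i in seq_len(n)) {
    v <- sweep(ca[-i, , drop = FALSE], 2, ca[i, ])
    d <- sqrt(rowSums(v^2))
    sel <- d > 0 & d <= radius
    if (!any(sel)) {
      lonely <- TRUE
      out[i] <- 0
      next
    }
    u <- v[sel, , drop = FALSE] / d[sel]
    out[i] <- 1 - sqrt(sum(colSums(u)^2)) / sum(sel)
  }
  if (lonely) warning("residue(s) with no neighbour within ", radius, " A: CV set to 0")
  out
}

#' Per-amino-acid interface propensity scores
#'
#' A bundled physico-chemical score in \[0, 1\] expressing how often each
#' residue type occurs in protein-protein interfaces relative to the rest
#' of the surface: aromatic and large hydrophobic types score high, charged
#' lysine/glutamate low. Authored for this package (min-max scaled from
#' widely reproduced interface-enrichment rankings); configurable by
#' passing a named vector wherever a descriptor table is built.
#'
#' @return Named numeric vector over the 20 amino-acid types.
#' @export
interface_propensity <- function() {
  c(TRP = 1.00, MET = 0.90, PHE = 0.88, TYR = 0.80, ILE = 0.67, CYS = 0.65,
    HIS = 0.60, LEU = 0.58, ARG = 0.55, VAL = 0.48, ASN = 0.40, THR = 0.32,
    ALA = 0.30, GLY = 0.28, SER = 0.25, GLN = 0.25, PRO = 0.20, ASP = 0.15,
    GLU = 0.05, LYS = 0.00)
}

#' Conservation fallback from a multiple sequence alignment
#'
#' Plumbing helper: per-column conservation as 1 minus the normalised
#' Shannon entropy of amino-acid frequencies (gaps ignored). This is a
#' simple stand-in used when no precomputed conservation table is supplied;
#' it does not emulate any particular conservation program.
#'
#' @param msa Character matrix, one aligned sequence per row, one-letter
#'   codes, `-` for gaps.
#' @return Numeric vector in \[0, 1\], one value per column.
#' @export
entropy_conservation <- function(msa) {
  msa <- as.matrix(msa)
  apply(msa, 2, function(col) {
    col <- col[col != "-" & col != "." & !is.na(col)]
    if (!length(col)) return(0)
    p <- table(col) / length(col)
    h <- -sum(p * log(p))
    1 - h / log(20)
  })
}

#' Docking-inferred residue binding propensity (NIP)
#'
#' For each surface residue of `protein_id`, counts how often it belongs to
#' the docked interface among the `top_k` lowest-energy conformations
#' against every partner in the store, then normalises by the maximum count
#' so that NIP spans \[0, 1\].
#'
#' @param store A `conformation_store` annotated by [docked_interfaces()].
#' @param protein_id Protein whose propensities are computed.
#' @param top_k Conformations counted per partner, default 10.
#' @param energy Column used to rank conformations, default `"e_maxdo"`.
#' @return Numeric vector over the protein's residues.
#' @export
nip_from_docking <- function(store, protein_id, top_k = 10, energy = "e_maxdo") {
  poses <- store$poses
  if (!protein_id %in% c(poses$receptor_id, poses$ligand_id)) {
    stop("protein ", protein_id, " absent from the conformation store")
  }
  if (!all(c("di_receptor", "di_ligand") %in% names(poses))) {
    stop("store has no docked interfaces; run docked_interfaces() first")
  }
  n_res <- nrow(store$proteins[[protein_id]]$residues)
  counts <- numeric(n_res)
  as_rec <- poses[poses$receptor_id == protein_id, , drop = FALSE]
  as_lig <- poses[poses$ligand_id == protein_id & poses$receptor_id != protein_id, , drop = FALSE]
  tally <- function(sub, side) {
    if (!nrow(sub)) return()
    partner <- if (side == "di_receptor") sub$ligand_id else sub$receptor_id
    for (p in unique(partner)) {
      pp <- sub[partner == p, , drop = FALSE]
      pp <- pp[order(pp[[energy]]), , drop = FALSE]
      pp <- pp[seq_len(min(top_k, nrow(pp))), , drop = FALSE]
      for (s in pp[[side]]) counts[s + 1L] <<- counts[s + 1L] + 1
    }
  }
  tally(as_rec, "di_receptor")
  tally(as_lig, "di_ligand")
  if (max(counts) > 0) counts / max(counts) else counts
}

#' Build a residue descriptor table for patch prediction
#'
#' Assembles the four per-residue descriptors used by the patch predictor,
#' all in \[0, 1\] and defined on surface residues: `tjet` (evolutionary
#' conservation, supplied externally or via [entropy_conservation()];
#' constant 0.5 when unavailable), `pc` (interface propensity of the
#' amino-acid type), `cv` (circular variance), `nip` (docking-inferred
#' binding propensity, 0 when no store is given).
#'
#' @param protein `atomic_protein` or `cg_protein`.
#' @param surface Per-residue logical surface mask (default: all surface).
#' @param tjet Optional per-residue conservation vector in \[0, 1\].
#' @param nip Optional per-residue NIP vector (see [nip_from_docking()]).
#' @param pc_table Named per-amino-acid propensity vector.
#' @param cv_radius Radius for the circular variance.
#' @return Tibble with columns `protein_id`, `res_idx`, `tjet`, `pc`, `cv`,
#'   `nip`, one row per surface residue.
#' @export
descriptor_table <- function(protein, surface = NULL, tjet = NULL, nip = NULL,
                             pc_table = interface_propensity(), cv_radius = 12) {
  n_res <- nrow(protein$residues)
  if (is.null(surface)) surface <- rep(TRUE, n_res)
  if (is.null(tjet)) tjet <- rep(0.5, n_res)
  if (is.null(nip)) nip <- rep(0, n_res)
  stopifnot(length(surface) == n_res, length(tjet) == n_res, length(nip) == n_res)
  cv <- circular_variance(protein, cv_radius)
  pc <- unname(pc_table[protein$residues$resid])
  pc[is.na(pc)] <- 0.5  # unknown residue types sit mid-scale
  tab <- tibble::tibble(protein_id = protein$protein_id,
                        res_idx = protein$residues$res_idx,
                        tjet = clamp01(tjet), pc = clamp01(pc),
                        cv = clamp01(cv), nip = clamp01(nip))
  tab[surface, , drop = FALSE]
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Scoring schemes of a patch-prediction strategy
#'
#' Four strategy families are available, each a set of member scoring
#' schemes with per-stage descriptor combinations (stage scores are the
#' product of the selected descriptors, circular variance entering as
#' 1 - CV):
#' \itemize{
#'   \item `SC-juxt`: the four juxtaposed single-protein schemes
#'     (`SC_cons`, `SC_notLig`, `SC_geom`, `SC_NIP`);
#'   \item `SC-mix`: the three single-protein schemes with NIP multiplied
#'     in at every stage;
#'   \item `SC-monoSeed-mix`: seeds detected without NIP, NIP mixed into
#'     extension and outer layer;
#'   \item `SC-dockSeed-mix`: seeds detected from NIP alone, growth using a
#'     combination of all four descriptors.
#' }
#'
#' @param family One of `"SC-juxt"`, `"SC-mix"`, `"SC-monoSeed-mix"`,
#'   `"SC-dockSeed-mix"`.
#' @return A `strategy_config`: list of scheme definitions, each with
#'   `name` and descriptor sets `seed`, `extend`, `outer` (`"cvc"` denotes
#'   1 - CV).
#' @export
strategy_config <- function(family = c("SC-dockSeed-mix", "SC-juxt", "SC-mix", "SC-monoSeed-mix")) {
  family <- match.arg(family)
  base <- list(
    cons   = list(seed = c("tjet"),        extend = c("tjet", "pc", "cvc"), outer = c("pc", "cvc")),
    notLig = list(seed = c("tjet", "cvc"), extend = c("tjet", "pc", "cvc"), outer = c("pc", "cvc")),
    geom   = list(seed = c("pc", "cvc"),   extend = c("pc", "cvc"),         outer = c("pc", "cvc"))
  )
  schemes <- switch(family,
    "SC-juxt" = c(
      lapply(names(base), function(nm) c(list(name = paste0("SC_", nm)), base[[nm]])),
      list(list(name = "SC_NIP", seed = "nip", extend = "nip", outer = "nip"))
    ),
    "SC-mix" = lapply(names(base), function(nm) {
      b <- base[[nm]]
      list(name = paste0("SC-mix_", nm), seed = union(b$seed, "nip"),
           extend = union(b$extend, "nip"), outer = union(b$outer, "nip"))
    }),
    "SC-monoSeed-mix" = lapply(names(base), function(nm) {
      b <- base[[nm]]
      list(name = paste0("SC-monoSeed_", nm), seed = b$seed,
           extend = union(b$extend, "nip"), outer = union(b$outer, "nip"))
    }),
    "SC-dockSeed-mix" = lapply(names(base), function(nm) {
      b <- base[[nm]]
      list(name = paste0("SC-dockSeed_", nm), seed = "nip",
           extend = union(b$extend, "nip"), outer = union(b$outer, "nip"))
    })
  )
  structure(list(family = family, schemes = schemes,
                 iterations = 10, min_votes = 2),
            class = "strategy_config")
}

stage_score <- function(descriptors, residues, set) {
  idx <- match(residues, descriptors$res_idx)
  s <- rep(1, length(residues))
  for (d in set) {
    v <- if (d == "cvc") 1 - descriptors$cv[idx] else descriptors[[d]][idx]
    s <- s * v
  }
  s
}

#' Grow one interface patch under a scoring scheme
#'
#' Three stages (seed, extension, outer layer). The seed stage scores every
#' surface residue with the scheme's seed descriptors, keeps the residues
#' above the seed percentile, clusters them on the surface graph, and picks
#' one cluster (sampling probability proportional to the cluster's summed
#' score, which is also the stochastic tie-break between runs). The
#' extension and outer stages repeatedly admit patch-adjacent residues whose
#' stage score is positive and above a percentile threshold re-estimated
#' among the current candidates.
#'
#' @param descriptors Descriptor table from [descriptor_table()].
#' @param scheme One scheme entry of a [strategy_config()].
#' @param graph [surface_graph()] of the protein.
#' @param thresholds Top fractions retained at the seed / extension / outer
#'   stages (defaults 0.15, 0.30, 0.40).
#' @param max_rounds Admission rounds per growth stage.
#' @return Integer vector of residue indices (empty, with a warning, when
#'   no seed can be detected).
#' @export
grow_patch <- function(descriptors, scheme, graph,
                       thresholds = c(seed = 0.15, extend = 0.30, outer = 0.40),
                       max_rounds = 5) {
  surf <- descriptors$res_idx
  if (!length(surf)) stop("empty surface")
  s_seed <- stage_score(descriptors, surf, scheme$seed)
  thr <- stats::quantile(s_seed, 1 - thresholds[["seed"]], names = FALSE, type = 7)
  cand <- surf[s_seed >= thr & s_seed > 0]
  if (!length(cand)) {
    warning("no seed residue for scheme ", scheme$name)
    return(integer(0))
  }
  clusters <- graph_components(graph, cand)
  w <- vapply(clusters, function(cl) sum(stage_score(descriptors, cl, scheme$seed)), numeric(1))
  pick <- if (length(clusters) == 1) 1 else sample.int(length(clusters), 1, prob = w)
  patch <- clusters[[pick]]
  for (stage in c("extend", "outer")) {
    p <- thresholds[[stage]]
    set <- scheme[[stage]]
    for (round in seq_len(max_rounds)) {
      nb <- setdiff(unique(unlist(lapply(patch, graph_neighbors, graph = graph))), patch)
      nb <- intersect(nb, surf)
      if (!length(nb)) break
      sc <- stage_score(descriptors, nb, set)
      thr <- stats::quantile(sc, 1 - p, names = FALSE, type = 7)
      # relative admission floor: joining residues must score comparably to
      # the patch they extend, so growth stops at the signal boundary
      floor_rel <- 0.5 * mean(stage_score(descriptors, patch, set))
      adm <- nb[sc >= thr & sc > 0 & sc >= floor_rel]
      if (!length(adm)) break
      patch <- sort(c(patch, adm))
    }
  }
  patch
}

#' Consensus interface patches over repeated runs
#'
#' Runs every member scheme of the strategy `iterations` times (default 10)
#' with the stochastic seed-cluster tie-break, keeps residues present in at
#' least `min_votes` runs (default 2) of a scheme, and clusters the kept
#' residues into connected patches on the surface graph.
#'
#' @param descriptors Descriptor table.
#' @param strategy A [strategy_config()].
#' @param graph Surface graph.
#' @param seed Integer seed for the whole prediction.
#' @param thresholds Stage thresholds, see [grow_patch()].
#' @return A `patch_prediction`: list with `protein_id`, `patches` (each a
#'   list with `residues` and per-residue `votes`), `family` and `seed`.
#' @export
consensus_patches <- function(descriptors, strategy, graph, seed = 1,
                              thresholds = c(seed = 0.15, extend = 0.30, outer = 0.40)) {
  stopifnot(inherits(strategy, "strategy_config"))
  patches <- list()
  withr::with_seed(seed, {
    for (scheme in strategy$schemes) {
      votes <- integer(0)
      for (it in seq_len(strategy$iterations)) {
        p <- suppressWarnings(grow_patch(descriptors, scheme, graph, thresholds))
        if (length(p)) {
          tab <- table(factor(p))
          for (r in names(tab)) votes[r] <- (if (r %in% names(votes)) votes[r] else 0L) + 1L
        }
      }
      keep <- as.integer(names(votes)[votes >= strategy$min_votes])
      if (!length(keep)) next
      for (cl in graph_components(graph, keep)) {
        patches[[length(patches) + 1]] <- list(
          residues = cl,
          votes = votes[as.character(cl)],
          scheme = scheme$name
        )
      }
    }
  })
  structure(list(protein_id = descriptors$protein_id[1], patches = patches,
                 family = strategy$family, seed = seed),
            class = "patch_prediction")
}

#' @export
print.patch_prediction <- function(x, ...) {
  cat("<patch_prediction> ", x$protein_id, " (", x$family, "): ",
      length(x$patches), " consensus patch(es)\n", sep = "")
  invisible(x)
}

#' Select the reference interface from predicted patches
#'
#' In oracle mode, enumerates all patches and unions of up to
#' `max_combination` patches and returns the one maximising F1 against the
#' known interface (the evaluation regime used when experimentally known
#' interfaces are available). In blind mode, returns the union of all
#' consensus patches.
#'
#' @param prediction A `patch_prediction`.
#' @param mode `"blind"` or `"oracle"`.
#' @param known Known `dm_interface` (required for oracle mode).
#' @param max_combination Largest union size enumerated in oracle mode.
#' @return A `dm_interface` with provenance `"predicted"` (empty, with a
#'   warning, if there are no patches).
#' @export
select_reference_interface <- function(prediction, mode = c("blind", "oracle"),
                                       known = NULL, max_combination = 3) {
  mode <- match.arg(mode)
  np <- length(prediction$patches)
  if (np == 0) {
    warning("no predicted patches for ", prediction$protein_id)
    return(suppressWarnings(new_interface(prediction$protein_id, integer(0), "predicted")))
  }
  sets <- lapply(prediction$patches, `[[`, "residues")
  if (mode == "blind") {
    return(new_interface(prediction$protein_id, unique(unlist(sets)), "predicted"))
  }
  if (is.null(known)) stop("oracle mode requires a known interface")
  best <- NULL
  best_f1 <- -1
  for (k in seq_len(min(max_combination, np))) {
    combos <- utils::combn(np, k, simplify = FALSE)
    for (cmb in combos) {
      u <- sort(unique(unlist(sets[cmb])))
      f1 <- interface_agreement(u, known)$f1
      if (f1 > best_f1) {
        best_f1 <- f1
        best <- u
      }
    }
  }
  out <- new_interface(prediction$protein_id, best, "predicted")
  attr(out, "f1") <- best_f1
  out
}
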