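#' Fraction of docked-interface residues inside the reference interfaces
#'
#' Per side, FIR is the fraction of the docked interface (DI) made of
#' residues that belong to the reference interface (RI); the pair value is
#' the product of the two sides. An empty docked interface gives FIR = 0.
#'
#' @param di_receptor,di_ligand Docked-interface residue index vectors.
#' @param ri_receptor,ri_ligand Reference interfaces (`dm_interface` or
#'   residue vectors) for the receptor and ligand.
#' @return FIR in \[0, 1\].
#' @export
fir <- function(di_receptor, di_ligand, ri_receptor, ri_ligand) {
  fir_side(di_receptor, ri_receptor) * fir_side(di_ligand, ri_ligand)
}

fir_side <- function(di, ri) {
  di <- iface_residues(di)
  if (!length(di)) return(0)
  length(intersect(di, iface_residues(ri))) / length(di)
}

#' Interaction index of one ordered protein pair
#'
#' \deqn{II = \min_c \; FIR_c \times E_c \;[\times PP_c],} the minimum over
#' the pair's docking conformations of the product of interface overlap,
#' docking energy (negative = favourable) and, optionally, a pair-potential
#' factor. If no conformation yields a negative product, II = 0 (no
#' favourable scored pose). With `pp_mode = "factor"` the pair-potential
#' scores are first mapped into \eqn{(0, 1]} with [pp_filter_transform()]
#' so that the product keeps the sign of the energy; `"raw"` multiplies the
#' scores in unchanged. `prefilter` optionally retains only the top
#' fraction of conformations by pair-potential score before the minimum.
#'
#' @param fir_values Per-conformation FIR values.
#' @param energy Per-conformation docking energies.
#' @param pp Per-conformation pair-potential scores, or `NULL` to omit the
#'   PP term.
#' @param pp_mode `"factor"` (default) or `"raw"`.
#' @param prefilter Optional fraction in (0, 1] of conformations retained
#'   (top PP scores) before taking the minimum.
#' @param pp_floor Floor of the factor map.
#' @return List with `ii` and `pose` (index of the minimising conformation,
#'   `NA` when II = 0 by convention).
#' @export
interaction_index <- function(fir_values, energy, pp = NULL,
                              pp_mode = c("factor", "raw"),
                              prefilter = NULL, pp_floor = 1e-3) {
  pp_mode <- match.arg(pp_mode)
  n <- length(fir_values)
  stopifnot(n >= 1, length(energy) == n)
  keep <- seq_len(n)
  if (!is.null(prefilter) && !is.null(pp)) {
    k <- max(1L, ceiling(prefilter * n))
    keep <- order(pp, decreasing = TRUE)[seq_len(k)]
  }
  prod <- fir_values[keep] * energy[keep]
  if (!is.null(pp)) {
    fac <- if (pp_mode == "factor") pp_filter_transform(pp[keep], pp_floor) else pp[keep]
    prod <- prod * fac
  }
  if (!any(is.finite(prod))) stop("no finite conformation product")
  best <- which.min(prod)
  if (prod[best] >= 0) {
    list(ii = 0, pose = NA_integer_)
  } else {
    list(ii = prod[best], pose = keep[best])
  }
}

#' Score every ordered pair of a conformation store
#'
#' Computes per-pose FIR against the proteins' reference interfaces and
#' reduces each ordered pair to its interaction index.
#'
#' @param store A `conformation_store` with docked interfaces (see
#'   [docked_interfaces()]; run automatically when `d` is given).
#' @param ris Named list of reference interfaces, one per protein id.
#' @param energy `"maxdo"`, `"iattract"` or `"external"`, selecting the
#'   pose score column (`e_maxdo`, `e_iattract`, `e_external`).
#' @param use_pp Include the pair-potential term (requires a `pp` column,
#'   see [add_pp_scores()] or planted scores).
#' @param pp_mode,prefilter,pp_floor Passed to [interaction_index()].
#' @param d Docked-interface distance threshold, used (and recorded) when
#'   the store has no interface annotation yet.
#' @return Tibble with one row per ordered pair: `receptor`, `ligand`,
#'   `fir_best`, `e_best`, `pp_best`, `ii`, `pose_best`.
#' @export
score_pairs <- function(store, ris, energy = c("maxdo", "iattract", "external"),
                        use_pp = FALSE, pp_mode = "factor", prefilter = NULL,
                        pp_floor = 1e-3, d = NULL) {
  energy <- match.arg(energy)
  if (!all(c("di_receptor", "di_ligand") %in% names(store$poses))) {
    if (is.null(d)) stop("store has no docked interfaces; pass d or run docked_interfaces()")
    store <- docked_interfaces(store, d)
  }
  ecol <- paste0("e_", energy)
  if (!ecol %in% names(store$poses)) stop("missing energy column: ", ecol)
  if (use_pp && !"pp" %in% names(store$poses)) stop("missing pair-potential column: pp")
  poses <- store$poses
  missing_ri <- setdiff(unique(c(poses$receptor_id, poses$ligand_id)), names(ris))
  if (length(missing_ri)) stop("no reference interface for: ", paste(missing_ri, collapse = ", "))
  keys <- paste(poses$receptor_id, poses$ligand_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(poses)), keys), function(rows) {
    sub <- poses[rows, , drop = FALSE]
    rid <- sub$receptor_id[1]; lid <- sub$ligand_id[1]
    fir_v <- vapply(seq_len(nrow(sub)), function(k) {
      fir(sub$di_receptor[[k]], sub$di_ligand[[k]], ris[[rid]], ris[[lid]])
    }, numeric(1))
    e_v <- sub[[ecol]]
    if (any(!is.finite(e_v))) stop("non-finite energies in column ", ecol, " for pair ", rid, "-", lid)
    pp_v <- if (use_pp) sub$pp else NULL
    res <- interaction_index(fir_v, e_v, pp_v, pp_mode = pp_mode,
                             prefilter = prefilter, pp_floor = pp_floor)
    b <- res$pose
    tibble::tibble(receptor = rid, ligand = lid,
                   fir_best = if (is.na(b)) NA_real_ else fir_v[b],
                   e_best = if (is.na(b)) NA_real_ else e_v[b],
                   pp_best = if (is.na(b) || is.null(pp_v)) NA_real_ else pp_v[b],
                   ii = res$ii,
                   pose_best = if (is.na(b)) NA_integer_ else sub$pose_id[b])
  })
  res <- dplyr::bind_rows(out)
  attr(res, "config") <- list(energy = energy, use_pp = use_pp, pp_mode = pp_mode,
                              prefilter = prefilter, d = store$d)
  res
}

ii_matrix <- function(tbl, value = "ii") {
  ids <- sort(unique(c(tbl$receptor, tbl$ligand)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(tbl$receptor, tbl$ligand)] <- tbl[[value]]
  m
}

#' Protein sociability (S-index)
#'
#' \deqn{S_{P_i} = \frac{1}{2|P|} \sum_{P_j \in P} (II_{P_i,P_j} + II_{P_j,P_i}),}
#' the protein's average interaction index over the whole set, both docking
#' directions, including its self-pair. Strongly negative S marks
#' indiscriminate "sticky" binders.
#'
#' @param ii_tbl Tibble with columns `receptor`, `ligand`, `ii` covering all
#'   ordered pairs (self-pairs included).
#' @return Tibble with `protein_id` and `s`.
#' @export
sociability <- function(ii_tbl) {
  m <- ii_matrix(ii_tbl)
  if (any(is.na(m))) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("missing ordered pair entries: ",
         paste(rownames(m)[miss[, 1]], colnames(m)[miss[, 2]], sep = "-", collapse = ", "))
  }
  n <- nrow(m)
  tibble::tibble(protein_id = rownames(m),
                 s = unname(rowSums(m) + colSums(m)) / (2 * n))
}

#' Sociability-normalised interaction indices
#'
#' First weights each index by the sociabilities of the two proteins,
#' \deqn{II'_{P_1,P_2} = II_{P_1,P_2} / \sqrt{|S_{P_1}| |S_{P_2}|},}
#' then symmetrises and rescales by the strongest indices each protein
#' achieves over the whole set:
#' \deqn{NII_{P_1,P_2} = \frac{\min(II'_{P_1,P_2}, II'_{P_2,P_1})}
#' {\left|\min_P II'_{P_1,P} \cdot \min_P II'_{P,P_2} \cdot
#' \min_P II'_{P,P_1} \cdot \min_P II'_{P_2,P}\right|^{1/4}}.}
#' Favourable energies being negative, minima pick the strongest
#' interactions; magnitudes are taken inside the square/fourth roots with
#' the numerator's sign carried through, and `eps` floors the denominators.
#'
#' @param ii_tbl Tibble with `receptor`, `ligand`, `ii` over all ordered pairs.
#' @param s Sociability tibble from [sociability()] (computed when `NULL`).
#' @param eps Magnitude floor for \eqn{|S|} and the denominator minima.
#' @return `ii_tbl` with columns `ii_prime` and `nii` added.
#' @export
normalized_ii <- function(ii_tbl, s = NULL, eps = 1e-9) {
  if (is.null(s)) s <- sociability(ii_tbl)
  if (all(abs(s$s) < eps)) stop("all sociabilities are zero (degenerate experiment)")
  m <- ii_matrix(ii_tbl)
  sv <- stats::setNames(s$s, s$protein_id)[rownames(m)]
  denom_s <- sqrt(outer(pmax(abs(sv), eps), pmax(abs(sv), eps)))
  iip <- m / denom_s
  row_min <- apply(iip, 1, min)  # min_P II'_{Pi,P}
  col_min <- apply(iip, 2, min)  # min_P II'_{P,Pj}
  n <- nrow(iip)
  nii <- matrix(NA_real_, n, n, dimnames = dimnames(iip))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- min(iip[i, j], iip[j, i])
      den <- (pmax(abs(row_min[i]), eps) * pmax(abs(col_min[j]), eps) *
                pmax(abs(col_min[i]), eps) * pmax(abs(row_min[j]), eps))^(1 / 4)
      nii[i, j] <- num / den
    }
  }
  ii_tbl$ii_prime <- iip[cbind(ii_tbl$receptor, ii_tbl$ligand)]
  ii_tbl$nii <- nii[cbind(ii_tbl$receptor, ii_tbl$ligand)]
  ii_tbl
}

#' Scale normalised indices into \[0, 1\] per focal protein
#'
#' Row-wise (per receptor protein), divides NII by the row's strongest
#' value under the sign convention (the most negative entry, or the largest
#' when no entry is negative), so the predicted best partner scores exactly
#' 1; results are clamped to \[0, 1\]. An all-zero row stays zero with a
#' warning.
#'
#' @param ii_tbl Tibble with a `nii` column (see [normalized_ii()]).
#' @return The tibble with `nii_scaled` added.
#' @export
scale_nii <- function(ii_tbl) {
  stopifnot("nii" %in% names(ii_tbl))
  groups <- split(seq_len(nrow(ii_tbl)), ii_tbl$receptor)
  scaled <- numeric(nrow(ii_tbl))
  zero_rows <- character(0)
  for (g in names(groups)) {
    rows <- groups[[g]]
    v <- ii_tbl$nii[rows]
    if (all(v == 0)) {
      scaled[rows] <- 0
      zero_rows <- c(zero_rows, g)
      next
    }
    extreme <- if (any(v < 0)) min(v) else max(v)
    scaled[rows] <- clamp01(v / extreme)
  }
  if (length(zero_rows)) warning("all-zero NII row(s): ", paste(zero_rows, collapse = ", "))
  ii_tbl$nii_scaled <- scaled
  ii_tbl
}

#' Assemble the interaction matrix of a scored protein set
#'
#' Runs sociability weighting, symmetrised normalisation and row scaling on
#' an interaction-index table, either over the whole set or within each
#' functional class.
#'
#' @param ii_tbl Pair table from [score_pairs()] (columns `receptor`,
#'   `ligand`, `ii`, plus any carried score columns).
#' @param scope `"all"` (default) normalises over the whole set;
#'   `"within-class"` restricts pairs and normalisation to each class.
#' @param classes Named character vector protein id -> class (required for
#'   within-class scope).
#' @param eps Denominator floor, see [normalized_ii()].
#' @return An `interaction_table` tibble with `ii_prime`, `nii`,
#'   `nii_scaled` columns; the sociability table is in
#'   `attr(, "sociability")` and the configuration in `attr(, "config")`.
#' @export
interaction_table <- function(ii_tbl, scope = c("all", "within-class"),
                              classes = NULL, eps = 1e-9) {
  scope <- match.arg(scope)
  cfg <- attr(ii_tbl, "config")
  if (scope == "all") {
    s <- sociability(ii_tbl)
    out <- scale_nii(normalized_ii(ii_tbl, s, eps))
  } else {
    if (is.null(classes)) stop("within-class scope requires a classes vector")
    ii_tbl <- ii_tbl[classes[ii_tbl$receptor] == classes[ii_tbl$ligand], , drop = FALSE]
    parts <- split(ii_tbl, classes[ii_tbl$receptor])
    s <- dplyr::bind_rows(lapply(parts, sociability))
    out <- dplyr::bind_rows(lapply(parts, function(p) {
      scale_nii(normalized_ii(p, sociability(p), eps))
    }))
  }
  structure(tibble::as_tibble(out),
            sociability = s,
            config = c(cfg, list(scope = scope)),
            class = c("interaction_table", class(tibble::tibble())))
}

#' @exportS3Method
tidy.interaction_table <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

unclass_tbl <- function(x) {
  attr(x, "sociability") <- NULL
  attr(x, "config") <- NULL
  class(x) <- class(tibble::tibble())
  x
}

#' @exportS3Method
glance.interaction_table <- function(x, ...) {
  s <- attr(x, "sociability")
  tibble::tibble(
    n_proteins = length(unique(c(x$receptor, x$ligand))),
    n_pairs = nrow(x),
    mean_sociability = mean(s$s),
    min_ii = min(x$ii),
    frac_favourable = mean(x$ii < 0)
  )
}

#' Heatmap of the scaled interaction matrix
#'
#' @param object An `interaction_table`.
#' @param value Column plotted, default `"nii_scaled"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.interaction_table <- function(object, value = "nii_scaled", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ligand, y = .data$receptor,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue", limits = c(NA, NA)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "ligand", y = "receptor", fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Write an interaction table and its sociability index to text files
#'
#' @param x An `interaction_table`.
#' @param path Path of the long-format pair table (TSV); the per-protein
#'   sociability table goes to `<path>` with suffix `"_sociability"`.
#' @export
write_interaction_table <- function(x, path) {
  utils::write.table(tidy(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- sub("(\\.[^.]*)?$", "_sociability\\1", path)
  utils::write.table(attr(x, "sociability"), spath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
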