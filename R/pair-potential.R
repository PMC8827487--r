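AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Train a residue-pair contact potential from bound complexes
#'
#' A standard interface log-odds potential: over all residue-level contacts
#' (any heavy-atom / pseudoatom distance strictly below `d`) found across
#' the training complexes, the score of the amino-acid type pair (a, b) is
#' \deqn{s(a,b) = \log\frac{f_{obs}(a,b) + \lambda}{f_{exp}(a,b) + \lambda},}
#' where \eqn{f_{obs}} is the observed frequency of the (unordered) type
#' pair among contacts and \eqn{f_{exp}} the product of the marginal
#' contact-endpoint type frequencies. The table is symmetric by
#' construction.
#'
#' @param complexes List of bound pairs; each element is a list with the two
#'   partners as elements `a` and `b` (`atomic_protein` or `cg_protein`).
#' @param d Contact distance, default 5 \eqn{\mathrm{\AA}}.
#' @param pseudocount Additive smoothing \eqn{\lambda}, default 1e-3.
#' @return A `contact_potential`: list with the 20x20 `table`, `d`,
#'   `pseudocount` and `n_contacts`.
#' @export
train_contact_potential <- function(complexes, d = 5, pseudocount = 1e-3) {
  stopifnot(length(complexes) >= 1)
  counts <- matrix(0, 20, 20, dimnames = list(AA3, AA3))
  for (cx in complexes) {
    a <- cx$a %||% cx[[1]]
    b <- cx$b %||% cx[[2]]
    cp <- contact_pairs(a, b, d)
    for (k in seq_len(nrow(cp))) {
      ta <- cp$type_a[k]; tb <- cp$type_b[k]
      if (ta %in% AA3 && tb %in% AA3) {
        counts[ta, tb] <- counts[ta, tb] + 1
        counts[tb, ta] <- counts[tb, ta] + 1
      }
    }
  }
  total <- sum(counts)
  if (total == 0) stop("no residue contacts in the training complexes")
  f_obs <- counts / total
  marg <- rowSums(counts) / total
  f_exp <- tcrossprod(marg)
  tab <- log((f_obs + pseudocount) / (f_exp + pseudocount))
  structure(list(table = tab, d = d, pseudocount = pseudocount,
                 n_contacts = total / 2,
                 training = paste(length(complexes), "complexes")),
            class = "contact_potential")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residue-level contact pairs between two structures under an optional
# transform of b; returns a tibble of residue index and type pairs
contact_pairs <- function(a, b, d, transform = NULL) {
  pa <- protein_atoms(a)
  pb <- protein_atoms(b)
  if (!is.null(transform)) pb$xyz <- apply_transform(pb$xyz, transform)
  hit <- cross_dist2(pa$xyz, pb$xyz) < d^2
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(tibble::tibble(res_a = integer(0), res_b = integer(0),
                          type_a = character(0), type_b = character(0)))
  }
  pairs <- unique(cbind(pa$res_idx[idx[, 1]], pb$res_idx[idx[, 2]]))
  ta <- residue_types(a)[pairs[, 1] + 1L]
  tb <- residue_types(b)[pairs[, 2] + 1L]
  tibble::tibble(res_a = pairs[, 1], res_b = pairs[, 2], type_a = ta, type_b = tb)
}

residue_types <- function(x) {
  if (is.list(x) && !is.null(x$residues)) x$residues$resid else rep("UNK", 10000L)
}

#' @export
print.contact_potential <- function(x, ...) {
  cat("<contact_potential> contact d = ", x$d, " A, ", x$n_contacts,
      " training contacts, range [", round(min(x$table), 3), ", ",
      round(max(x$table), 3), "]\n", sep = "")
  invisible(x)
}

#' Score a docked conformation with a contact potential
#'
#' Sums the potential's table entries over all residue-residue contacts
#' across the docked interface; higher scores mark more native-like
#' residue pairings. Residue types absent from the table contribute 0.
#'
#' @param receptor,ligand The two structures.
#' @param potential A `contact_potential`.
#' @param transform Optional `rigid_transform` applied to the ligand.
#' @param d Contact distance; defaults to the potential's own.
#' @return Scalar score (0 when there are no contacts).
#' @export
pp_score <- function(receptor, ligand, potential, transform = NULL, d = NULL) {
  stopifnot(inherits(potential, "contact_potential"))
  if (is.null(d)) d <- potential$d
  cp <- contact_pairs(receptor, ligand, d, transform)
  if (!nrow(cp)) return(0)
  known <- cp$type_a %in% rownames(potential$table) & cp$type_b %in% colnames(potential$table)
  sum(potential$table[cbind(cp$type_a[known], cp$type_b[known])])
}

#' Map pair-potential scores to positive filter factors
#'
#' Affine min-max map of a pair's per-conformation scores into
#' \eqn{(0, 1]}: \eqn{f = \delta + (1-\delta)(s - \min s)/(\max s - \min s)},
#' so the best-scoring conformation gets exactly 1, the worst gets the
#' floor \eqn{\delta}, ordering is preserved, and multiplying a negative
#' docking energy by the factor cannot flip its sign. Constant scores map
#' to all 1.
#'
#' @param scores Numeric vector of pair-potential scores over one pair's
#'   conformations.
#' @param floor Positive floor \eqn{\delta}, default 1e-3.
#' @return Factors in \eqn{(0, 1]}, same length as `scores`.
#' @export
pp_filter_transform <- function(scores, floor = 1e-3) {
  stopifnot(length(scores) >= 1, floor > 0, floor < 1)
  rng <- range(scores)
  if (rng[2] - rng[1] < .Machine$double.eps) return(rep(1, length(scores)))
  x <- (scores - rng[1]) / (rng[2] - rng[1])
  floor + (1 - floor) * x
}

#' Add pair-potential scores to a conformation store
#'
#' Scores every pose with [pp_score()] and stores the result in a `pp`
#' column.
#'
#' @param store A `conformation_store`.
#' @param potential A `contact_potential`.
#' @return The store with a `pp` column.
#' @export
add_pp_scores <- function(store, potential) {
  poses <- store$poses
  pp <- numeric(nrow(poses))
  for (k in seq_len(nrow(poses))) {
    pp[k] <- pp_score(store$proteins[[poses$receptor_id[k]]],
                      store$proteins[[poses$ligand_id[k]]],
                      potential, transform = poses$transform[[k]])
  }
  store$poses$pp <- pp
  store
}

#' Write / read a contact potential as labelled tab-separated text
#'
#' The 20x20 table is written at full precision with the contact distance
#' and pseudocount in comment headers, so that a read round-trip is exact.
#'
#' @param potential A `contact_potential`.
#' @param path File path.
#' @export
write_contact_potential <- function(potential, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# contact_potential d=", format(potential$d, digits = 17),
           " pseudocount=", format(potential$pseudocount, digits = 17),
           " n_contacts=", format(potential$n_contacts, digits = 17)),
    paste(c("aa", colnames(potential$table)), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(potential$table))) {
    writeLines(paste(c(rownames(potential$table)[i],
                       format(potential$table[i, ], digits = 17)), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_contact_potential
#' @export
read_contact_potential <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# contact_potential ", "", lines[1]), " ")[[1]]
  kv <- stats::setNames(
    as.numeric(sub("^[a-z_]+=", "", hdr)),
    sub("=.*$", "", hdr)
  )
  tab <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE, row.names = 1)
  tab <- as.matrix(tab)
  structure(list(table = tab, d = unname(kv["d"]),
                 pseudocount = unname(kv["pseudocount"]),
                 n_contacts = unname(kv["n_contacts"]),
                 training = "read from file"),
            class = "contact_potential")
}
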