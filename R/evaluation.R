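#' Partner-discrimination AUC
#'
#' Rank-sum (Mann-Whitney) AUC of the known interacting pairs against all
#' other candidate pairs, over the scaled interaction indices. Ties get
#' mid-ranks; self-pairs are excluded by default.
#'
#' @param scores An `interaction_table` or tibble with `receptor`, `ligand`
#'   and a score column.
#' @param positives Data frame of known pairs (first two columns are the
#'   protein ids); both orientations of a listed pair count as positive.
#' @param value Score column, default `"nii_scaled"`.
#' @param scope `"all"`, or `"within-class"` to keep only same-class pairs.
#' @param classes Named protein id -> class vector for within-class scope.
#' @param include_self Keep self-pairs as candidates (default FALSE).
#' @return AUC in \[0, 1\].
#' @export
auc_partner <- function(scores, positives, value = "nii_scaled",
                        scope = c("all", "within-class"), classes = NULL,
                        include_self = FALSE) {
  scope <- match.arg(scope)
  df <- tibble::as_tibble(scores)[, c("receptor", "ligand", value)]
  if (!include_self) df <- df[df$receptor != df$ligand, , drop = FALSE]
  if (scope == "within-class") {
    if (is.null(classes)) stop("within-class scope requires a classes vector")
    df <- df[classes[df$receptor] == classes[df$ligand], , drop = FALSE]
  }
  lab <- pair_labels(df, positives)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) stop("degenerate scope: need at least one positive and one negative pair")
  r <- rank(df[[value]])
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

pair_labels <- function(df, positives) {
  positives <- as.data.frame(positives)
  key_pos <- c(paste(positives[[1]], positives[[2]], sep = "\r"),
               paste(positives[[2]], positives[[1]], sep = "\r"))
  paste(df$receptor, df$ligand, sep = "\r") %in% key_pos
}

#' Weighted average AUC over subsets
#'
#' \deqn{\overline{AUC} = \sum_j N_j AUC_j / \sum_j N_j,} the subset-size
#' weighted mean used to rank hyper-parameter combinations (typically over
#' the functional classes plus the entire set).
#'
#' @param aucs Per-subset AUC values.
#' @param sizes Per-subset protein counts (positive).
#' @return Weighted mean AUC.
#' @export
weighted_auc <- function(aucs, sizes) {
  if (length(aucs) != length(sizes)) stop("aucs and sizes differ in length")
  stopifnot(all(sizes > 0))
  sum(sizes * aucs) / sum(sizes)
}

#' Hyper-parameter grid for the scoring pipeline
#'
#' The full factorial grid over the docked-interface distance threshold,
#' the patch-prediction strategy (dropped when reference interfaces are
#' experimental), the docking energy and the pair-potential flag:
#' 3 x 4 x 3 x 2 = 72 combinations with predicted reference interfaces,
#' 3 x 3 x 2 = 18 with experimental ones.
#'
#' @param ri_source `"predicted"` or `"experimental"`.
#' @param distances,strategies,energies,pp Value sets of each parameter.
#' @return Tibble of combinations, one per row, with a `combo` id column.
#' @export
hyper_grid <- function(ri_source = c("predicted", "experimental"),
                       distances = c(4.5, 5, 6),
                       strategies = c("SC-mix", "SC-monoSeed-mix", "SC-dockSeed-mix", "SC-juxt"),
                       energies = c("maxdo", "iattract", "external"),
                       pp = c(TRUE, FALSE)) {
  ri_source <- match.arg(ri_source)
  g <- if (ri_source == "predicted") {
    tidyr::expand_grid(distance = distances, strategy = strategies,
                       energy = energies, pp = pp)
  } else {
    tidyr::expand_grid(distance = distances, energy = energies, pp = pp)
  }
  g$combo <- seq_len(nrow(g))
  attr(g, "ri_source") <- ri_source
  g
}

#' Grid search over scoring hyper-parameters
#'
#' Evaluates every combination of the grid with a user-supplied runner,
#' ranks combinations by their subset-size weighted AUC, picks the global
#' default, and, per subset, retains the top `retain_frac` fraction
#' (ceiling) of combinations and partitions that pool by each parameter's
#' values (mean, max and mean +/- 2 SEM per value). Whenever a
#' non-default parameter value has a higher pool mean than the default for
#' a subset, the full per-value AUC distributions are compared with a
#' two-sided Mann-Whitney U test and the value overrides the default for
#' that subset at p < `alpha`.
#'
#' @param runner Function called as `runner(combo_row)`, returning a data
#'   frame with columns `subset`, `auc` and `n` (subset size). Failing
#'   combinations are excluded with a warning.
#' @param grid A [hyper_grid()] tibble.
#' @param retain_frac Fraction of top combinations pooled per subset
#'   (default 0.20 for the predicted-interface grid, use 0.30 for the
#'   experimental one).
#' @param alpha Override significance level, default 0.01.
#' @return A `dockmate_grid` list: `results` (combo x subset AUC long
#'   tibble), `grid`, `default` (row of the best combination), `pool`,
#'   `partitions`, `overrides`, `per_subset` (recommended parameter values
#'   after overrides).
#' @export
grid_search <- function(runner, grid = hyper_grid(), retain_frac = 0.20, alpha = 0.01) {
  res <- vector("list", nrow(grid))
  failed <- integer(0)
  for (i in seq_len(nrow(grid))) {
    out <- tryCatch(runner(grid[i, ]), error = function(e) e)
    if (inherits(out, "error")) {
      failed <- c(failed, grid$combo[i])
      next
    }
    out <- tibble::as_tibble(out)
    out$combo <- grid$combo[i]
    res[[i]] <- out
  }
  if (length(failed)) {
    warning("combination(s) failed and were excluded: ", paste(failed, collapse = ", "))
    grid <- grid[!grid$combo %in% failed, , drop = FALSE]
  }
  results <- dplyr::bind_rows(res)
  if (!nrow(results)) stop("every grid combination failed")
  params <- setdiff(names(grid), "combo")
  # weighted average AUC per combination
  wtab <- results |>
    dplyr::group_by(.data$combo) |>
    dplyr::summarise(weighted_auc = weighted_auc(.data$auc, .data$n), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$weighted_auc))
  default <- grid[grid$combo == wtab$combo[1], , drop = FALSE]
  n_comb <- nrow(grid)
  pool_size <- ceiling(retain_frac * n_comb)
  subsets <- unique(results$subset)
  pool <- dplyr::bind_rows(lapply(subsets, function(sb) {
    sub <- results[results$subset == sb, , drop = FALSE]
    sub <- sub[order(-sub$auc, sub$combo), , drop = FALSE]
    sub[seq_len(min(pool_size, nrow(sub))), , drop = FALSE]
  }))
  pool <- dplyr::left_join(pool, grid, by = "combo")
  partitions <- dplyr::bind_rows(lapply(params, function(pm) {
    pool |>
      dplyr::group_by(.data$subset, value = as.character(.data[[pm]])) |>
      dplyr::summarise(parameter = pm, n = dplyr::n(), mean_auc = mean(.data$auc),
                       max_auc = max(.data$auc),
                       sem = stats::sd(.data$auc) / sqrt(dplyr::n()), .groups = "drop") |>
      dplyr::mutate(lo = .data$mean_auc - 2 * ifelse(is.na(.data$sem), 0, .data$sem),
                    hi = .data$mean_auc + 2 * ifelse(is.na(.data$sem), 0, .data$sem))
  }))
  full <- dplyr::left_join(results, grid, by = "combo")
  overrides <- list()
  per_subset <- list()
  for (sb in subsets) {
    choice <- as.list(default[1, params])
    for (pm in params) {
      dv <- as.character(default[[pm]][1])
      part <- partitions[partitions$subset == sb & partitions$parameter == pm, , drop = FALSE]
      dmean <- if (dv %in% part$value) part$mean_auc[part$value == dv] else -Inf
      cand <- setdiff(part$value[part$mean_auc > dmean], dv)
      for (cv in cand) {
        mw <- mwu_override(
          full$auc[full$subset == sb & as.character(full[[pm]]) == dv],
          full$auc[full$subset == sb & as.character(full[[pm]]) == cv],
          alpha = alpha
        )
        overrides[[length(overrides) + 1]] <- tibble::tibble(
          subset = sb, parameter = pm, default = dv, alternative = cv,
          p_value = mw$p_value, override = mw$override
        )
        if (mw$override) choice[[pm]] <- utils::type.convert(cv, as.is = TRUE)
      }
    }
    per_subset[[sb]] <- tibble::as_tibble(c(list(subset = sb), choice))
  }
  structure(list(results = results, grid = grid, default = default,
                 weighted = wtab, pool = pool, pool_size = pool_size,
                 partitions = partitions,
                 overrides = dplyr::bind_rows(overrides),
                 per_subset = dplyr::bind_rows(per_subset)),
            class = "dockmate_grid")
}

#' @export
print.dockmate_grid <- function(x, ...) {
  cat("<grid_search> ", nrow(x$grid), " combinations, pool size ", x$pool_size,
      "\n  default: ", paste(names(x$default)[names(x$default) != "combo"],
                             vapply(x$default[names(x$default) != "combo"], as.character, character(1)),
                             sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.dockmate_grid <- function(x, ...) x$partitions

#' @exportS3Method
glance.dockmate_grid <- function(x, ...) {
  tibble::tibble(n_combinations = nrow(x$grid), pool_size = x$pool_size,
                 best_weighted_auc = x$weighted$weighted_auc[1],
                 n_overrides = sum(x$overrides$override))
}

#' Bar chart of per-parameter AUC partitions of the retained pool
#' @param object A `dockmate_grid`.
#' @param ... Unused.
#' @exportS3Method
autoplot.dockmate_grid <- function(object, ...) {
  ggplot2::ggplot(object$partitions,
                  ggplot2::aes(x = .data$value, y = .data$mean_auc, fill = .data$value)) +
    ggplot2::geom_col(alpha = 0.9) +
    ggplot2::geom_col(ggplot2::aes(y = .data$max_auc), alpha = 0.3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi), width = 0.3) +
    ggplot2::facet_grid(subset ~ parameter, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "AUC (pool mean, max, mean +/- 2 SEM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Mann-Whitney override decision between two parameter values
#'
#' Two-sided Mann-Whitney U test (tie-corrected normal approximation)
#' between the AUC distributions obtained with the default and an
#' alternative parameter value over the full grid; the alternative
#' overrides the default iff its mean AUC is higher and p < `alpha`.
#'
#' @param default_aucs,alt_aucs AUC samples for the two values.
#' @param alpha Significance level, default 0.01.
#' @return List with `override`, `p_value`, `mean_default`, `mean_alt`, `u`.
#' @export
mwu_override <- function(default_aucs, alt_aucs, alpha = 0.01) {
  if (!length(default_aucs) || !length(alt_aucs)) {
    return(list(override = FALSE, p_value = NA_real_,
                mean_default = NA_real_, mean_alt = NA_real_, u = NA_real_))
  }
  wt <- suppressWarnings(stats::wilcox.test(alt_aucs, default_aucs,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(override = mean(alt_aucs) > mean(default_aucs) && wt$p.value < alpha,
       p_value = wt$p.value,
       mean_default = mean(default_aucs), mean_alt = mean(alt_aucs),
       u = unname(wt$statistic))
}

#' Best known-partner ranks per protein
#'
#' Ranks each protein's candidate partners by decreasing score (ties broken
#' by protein id) and returns the best rank achieved by a known partner.
#'
#' @inheritParams auc_partner
#' @return Tibble with `protein_id`, `best_rank`, `n_candidates`,
#'   `n_partners`.
#' @export
partner_ranks <- function(scores, positives, value = "nii_scaled", include_self = FALSE) {
  df <- tibble::as_tibble(scores)[, c("receptor", "ligand", value)]
  if (!include_self) df <- df[df$receptor != df$ligand, , drop = FALSE]
  lab <- pair_labels(df, positives)
  out <- lapply(split(seq_len(nrow(df)), df$receptor), function(rows) {
    sub <- df[rows, , drop = FALSE]
    ord <- order(-sub[[value]], sub$ligand)
    pos <- which(lab[rows][ord])
    tibble::tibble(protein_id = sub$receptor[1],
                   best_rank = if (length(pos)) min(pos) else NA_integer_,
                   n_candidates = nrow(sub),
                   n_partners = length(pos))
  })
  dplyr::bind_rows(out)
}

#' Proportion of proteins with a known partner in the top X%
#'
#' \deqn{P_{topX} = \frac{1}{N_{prot}} \sum_i 1\left[\min_k R_k^i \le \frac{X}{100} N\right]}
#' over the proteins' best known-partner ranks.
#'
#' @param best_ranks Per-protein best known-partner ranks (in \[1, N\]).
#' @param x Percentage threshold X.
#' @param n_candidates Number of candidate partners N (scalar or
#'   per-protein vector).
#' @return Proportion in \[0, 1\].
#' @export
ptopx <- function(best_ranks, x, n_candidates) {
  n <- rep_len(n_candidates, length(best_ranks))
  ok <- !is.na(best_ranks)
  if (any(best_ranks[ok] < 1 | best_ranks[ok] > n[ok])) stop("rank out of [1, N]")
  mean(ok & best_ranks <= (x / 100) * n, na.rm = FALSE)
}

#' Partner-count baseline for the top X% proportion
#'
#' \deqn{P_{topX}^{base} = \frac{1}{N_{prot}} \sum_i 1\left[\frac{X}{100} N_i \ge 1\right],}
#' the proportion of proteins for which the expected number of known
#' partners in a random X% subset is at least one.
#'
#' @param n_partners Per-protein known-partner counts \eqn{N_i}.
#' @param x Percentage threshold X.
#' @return Proportion in \[0, 1\].
#' @export
baseline_ptopx <- function(n_partners, x) {
  stopifnot(all(n_partners >= 0))
  mean((x / 100) * n_partners >= 1)
}

#' Top-X% enrichment curve with its baseline
#'
#' @inheritParams auc_partner
#' @param xs Percentages evaluated.
#' @return A `ptopx_curve` tibble with `x`, `ptopx`, `baseline`.
#' @export
ptopx_curve <- function(scores, positives, xs = seq(5, 100, by = 5),
                        value = "nii_scaled", include_self = FALSE) {
  pr <- partner_ranks(scores, positives, value, include_self)
  out <- tibble::tibble(
    x = xs,
    ptopx = vapply(xs, function(x) {
      ptopx(ifelse(is.na(pr$best_rank), pr$n_candidates, pr$best_rank), x, pr$n_candidates)
    }, numeric(1)),
    baseline = vapply(xs, function(x) baseline_ptopx(pr$n_partners, x), numeric(1))
  )
  class(out) <- c("ptopx_curve", class(out))
  out
}

#' @exportS3Method
autoplot.ptopx_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("ptopx", "baseline"),
                            names_to = "series", values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$proportion,
                                   linetype = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "top X% of predictions", y = "proteins with a known partner") +
    ggplot2::theme_minimal()
}

#' Extend known interacting pairs by homology transfer
#'
#' A protein pair is positive iff some experimentally characterised complex
#' puts a cluster-mate of one of its chains in contact (interface strictly
#' larger than `min_interface` residues) with a cluster-mate of a chain of
#' the other protein. Multi-chain proteins are positive as soon as one
#' chain pair is in interaction. Chains without a cluster assignment are
#' treated as singleton clusters (logged as a message).
#'
#' @param contacts Data frame of chain-level complexes: columns `chain_a`,
#'   `chain_b`, `n_interface`.
#' @param clusters Data frame mapping `chain` to `cluster` (one sequence
#'   identity level per call).
#' @param protein_chains Data frame mapping `protein_id` to `chain`.
#' @param min_interface Minimum interface size, strict (default 5: a
#'   6-residue interface transfers, a 5-residue one does not).
#' @return Tibble of positive protein pairs (`a`, `b`, unordered, a <= b).
#' @export
homology_transfer <- function(contacts, clusters, protein_chains, min_interface = 5) {
  contacts <- tibble::as_tibble(contacts)
  clusters <- tibble::as_tibble(clusters)
  protein_chains <- tibble::as_tibble(protein_chains)
  all_chains <- unique(c(protein_chains$chain, contacts$chain_a, contacts$chain_b))
  unassigned <- setdiff(all_chains, clusters$chain)
  if (length(unassigned)) {
    message(length(unassigned), " chain(s) without cluster assignment treated as singletons")
    clusters <- dplyr::bind_rows(
      clusters,
      tibble::tibble(chain = unassigned, cluster = paste0("singleton:", unassigned))
    )
  }
  cl <- stats::setNames(clusters$cluster, clusters$chain)
  valid <- contacts[contacts$n_interface > min_interface, , drop = FALSE]
  # cluster pairs in contact (unordered)
  cp <- unique(rbind(
    cbind(cl[valid$chain_a], cl[valid$chain_b]),
    cbind(cl[valid$chain_b], cl[valid$chain_a])
  ))
  pc <- dplyr::mutate(protein_chains, cluster = cl[.data$chain])
  join <- dplyr::inner_join(
    dplyr::inner_join(tibble::tibble(cluster_a = cp[, 1], cluster_b = cp[, 2]),
                      dplyr::rename(pc, protein_a = "protein_id", cluster_a = "cluster"),
                      by = "cluster_a", relationship = "many-to-many"),
    dplyr::rename(pc, protein_b = "protein_id", cluster_b = "cluster"),
    by = "cluster_b", relationship = "many-to-many"
  )
  if (!nrow(join)) return(tibble::tibble(a = character(0), b = character(0)))
  pairs <- tibble::tibble(a = pmin(join$protein_a, join$protein_b),
                          b = pmax(join$protein_a, join$protein_b))
  dplyr::distinct(pairs)
}
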