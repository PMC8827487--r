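mk_scores <- function(ids, fn) {
  df <- tidyr::expand_grid(receptor = ids, ligand = ids)
  df <- df[df$receptor != df$ligand, ]
  df$nii_scaled <- fn(nrow(df))
  df
}

test_that("AUC is 1 for perfectly separated scores and matches the U identity", {
  ids <- paste0("p", 1:4)
  pos <- tibble::tibble(a = c("p1", "p3"), b = c("p2", "p4"))
  df <- tidyr::expand_grid(receptor = ids, ligand = ids)
  df <- df[df$receptor != df$ligand, ]
  lab <- dockmate:::pair_labels(df, pos)
  df$nii_scaled <- ifelse(lab, 1, 0)
  expect_equal(auc_partner(df, pos), 1)
  # hand scores: AUC equals U / (n1 n2) from exhaustive pair counting
  set.seed(4)
  df$nii_scaled <- round(runif(nrow(df)), 1)  # induce ties
  expect_equal(auc_partner(df, pos), bf_auc(df$nii_scaled, lab))
})

test_that("label permutation centres the AUC distribution at one half", {
  ids <- paste0("p", 1:6)
  df <- tidyr::expand_grid(receptor = ids, ligand = ids)
  df <- df[df$receptor != df$ligand, ]
  set.seed(10)
  df$nii_scaled <- runif(nrow(df))
  aucs <- replicate(1000, {
    lab <- sample(c(rep(TRUE, 5), rep(FALSE, nrow(df) - 5)))
    bf_auc(df$nii_scaled, lab)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("degenerate scopes are rejected", {
  ids <- c("a", "b")
  df <- mk_scores(ids, function(n) runif(n))
  expect_error(auc_partner(df, tibble::tibble(a = "a", b = "b")), "degenerate")
  expect_error(auc_partner(df, tibble::tibble(a = character(0), b = character(0))),
               "degenerate")
})

test_that("weighted AUC is the size-weighted mean", {
  expect_equal(weighted_auc(c(0.5, 0.9), c(10, 30)), 0.8)
  expect_equal(weighted_auc(c(0.6, 0.8), c(7, 7)), 0.7)
  set.seed(6)
  a <- runif(9); n <- sample(5:50, 9)
  expect_equal(weighted_auc(a, n), sum(a * n) / sum(n))
  expect_error(weighted_auc(c(0.5, 0.6), 1), "length")
})

test_that("hyper-parameter grids have the documented sizes", {
  expect_equal(nrow(hyper_grid("predicted")), 72)
  expect_equal(nrow(hyper_grid("experimental")), 18)
})

test_that("grid search retains the documented pools and recovers a planted optimum", {
  grid <- hyper_grid("predicted")
  best <- list(distance = 6, strategy = "SC-dockSeed-mix", energy = "maxdo", pp = TRUE)
  runner <- function(combo) {
    # planted structure: bonus for each matching parameter + deterministic jitter
    strat_bonus <- if ("strategy" %in% names(combo)) {
      0.08 * (combo$strategy == best$strategy)
    } else 0
    score <- 0.5 +
      0.05 * (combo$distance == best$distance) +
      strat_bonus +
      0.04 * (combo$energy == best$energy) +
      0.02 * (combo$pp == best$pp)
    tibble::tibble(subset = c("all", "c1", "c2"),
                   auc = score + c(0, 0.01, -0.01) + combo$combo * 1e-5,
                   n = c(20, 12, 8))
  }
  gs <- grid_search(runner, grid, retain_frac = 0.20)
  expect_equal(gs$pool_size, 15)   # ceil(0.20 * 72)
  expect_equal(gs$default$distance, best$distance)
  expect_equal(gs$default$strategy, best$strategy)
  expect_equal(gs$default$energy, best$energy)
  expect_equal(gs$default$pp, best$pp)
  # every subset retains exactly pool_size combinations
  expect_equal(unname(table(gs$pool$subset)), rep(15L, 3) , ignore_attr = TRUE)
  gs18 <- grid_search(runner, hyper_grid("experimental"), retain_frac = 0.30)
  expect_equal(gs18$pool_size, 6)  # ceil(0.30 * 18)
  # failing combinations are excluded with a warning, grid size reported accordingly
  runner_fail <- function(combo) {
    if (combo$combo == 1) stop("boom")
    runner(combo)
  }
  expect_warning(gsf <- grid_search(runner_fail, grid), "excluded")
  expect_equal(nrow(gsf$grid), 71)
})

test_that("Mann-Whitney overrides fire only for significantly better alternatives", {
  set.seed(33)
  same <- rnorm(24, 0.7, 0.05)
  r1 <- mwu_override(same, same)
  expect_false(r1$override)
  expect_gt(r1$p_value, 0.9)
  # completely separated distributions with n = 24 each
  lo <- runif(24, 0.5, 0.6)
  hi <- runif(24, 0.8, 0.9)
  r2 <- mwu_override(lo, hi)
  expect_true(r2$override)
  expect_lt(r2$p_value, 0.01)
  # higher mean required: a significantly WORSE alternative never overrides
  r3 <- mwu_override(hi, lo)
  expect_false(r3$override)
  # small-sample U equals the exhaustive pair-count definition
  x <- c(0.5, 0.7, 0.9); y <- c(0.6, 0.8)
  r4 <- mwu_override(x, y)
  expect_equal(unname(r4$u), bf_mwu_u(y, x))
  # empty partition: no override
  expect_false(mwu_override(numeric(0), hi)$override)
})

test_that("PtopX counts boundary ranks as printed", {
  # N = 10, X = 20: best rank 2 counted (2 <= 2), rank 3 not
  expect_equal(ptopx(2, 20, 10), 1)
  expect_equal(ptopx(3, 20, 10), 0)
  expect_error(ptopx(11, 20, 10), "rank")
  set.seed(9)
  ranks <- sample(1:30, 25, replace = TRUE)
  for (x in c(10, 20, 50)) {
    expect_equal(ptopx(ranks, x, 30), mean(ranks <= x / 100 * 30))
  }
  # non-decreasing in X
  xs <- seq(5, 100, 5)
  curve <- vapply(xs, function(x) ptopx(ranks, x, 30), numeric(1))
  expect_true(all(diff(curve) >= 0))
})

test_that("the partner-count baseline follows the printed indicator", {
  expect_equal(baseline_ptopx(5, 20), 1)   # 0.2 * 5 = 1 >= 1
  expect_equal(baseline_ptopx(4, 20), 0)   # 0.8 < 1
  ni <- c(0, 1, 2, 5, 10)
  expect_equal(baseline_ptopx(ni, 20), mean(ni * 0.2 >= 1))
  # non-decreasing in X and in each partner count
  for (x in c(10, 20, 40, 80)) {
    expect_true(baseline_ptopx(ni, x) <= baseline_ptopx(ni + 1, x))
  }
  xs <- c(5, 10, 25, 50, 100)
  curve <- vapply(xs, baseline_ptopx, numeric(1), n_partners = ni)
  expect_true(all(diff(curve) >= 0))
})

test_that("best-rank extraction and enrichment curves work on planted ranks", {
  ids <- paste0("p", 1:6)
  df <- tidyr::expand_grid(receptor = ids, ligand = ids)
  df <- df[df$receptor != df$ligand, ]
  # plant: p2 is p1's best partner with the top score in p1's row
  set.seed(2)
  df$nii_scaled <- runif(nrow(df), 0, 0.5)
  df$nii_scaled[df$receptor == "p1" & df$ligand == "p2"] <- 1
  pos <- tibble::tibble(a = "p1", b = "p2")
  pr <- partner_ranks(df, pos)
  expect_equal(pr$best_rank[pr$protein_id == "p1"], 1L)
  expect_equal(pr$n_candidates, rep(5L, 6))
  cv <- ptopx_curve(df, pos, xs = c(20, 100))
  expect_equal(cv$ptopx[cv$x == 100], 1)  # every protein has a partner in the full list
  expect_s3_class(ggplot2::autoplot(cv), "gg")
})

test_that("homology transfer joins cluster-mates with the strict interface filter", {
  # chains: proteins P1 = {A1}, P2 = {B1}, P3 = {C1, C2}
  protein_chains <- tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P3"),
    chain = c("A1", "B1", "C1", "C2")
  )
  clusters <- tibble::tibble(
    chain = c("A1", "H1", "B1", "H2", "C1"),
    cluster = c("k1", "k1", "k2", "k2", "k3")
  )
  # homolog complex H1-H2 with 6 interface residues -> transfers to P1-P2;
  # a 5-residue contact must NOT transfer; C2 is unassigned (singleton)
  contacts <- tibble::tibble(
    chain_a = c("H1", "C1"),
    chain_b = c("H2", "B1"),
    n_interface = c(6, 5)
  )
  expect_message(pos <- homology_transfer(contacts, clusters, protein_chains),
                 "singleton")
  expect_equal(nrow(pos), 1)
  expect_equal(pos$a, "P1")
  expect_equal(pos$b, "P2")
  # raising the contact to 6 residues brings the multi-chain protein in
  contacts$n_interface[2] <- 6
  pos2 <- suppressMessages(homology_transfer(contacts, clusters, protein_chains))
  expect_true(any(pos2$a == "P2" & pos2$b == "P3"))
  # exhaustive relational-join oracle on a planted random instance
  set.seed(44)
  chains <- paste0("c", 1:12)
  pc <- tibble::tibble(protein_id = paste0("P", rep(1:6, each = 2)), chain = chains)
  cl <- tibble::tibble(chain = chains, cluster = sample(paste0("k", 1:4), 12, replace = TRUE))
  ct <- tibble::tibble(chain_a = sample(chains, 8, replace = TRUE),
                       chain_b = sample(chains, 8, replace = TRUE),
                       n_interface = sample(3:9, 8, replace = TRUE))
  got <- suppressMessages(homology_transfer(ct, cl, pc))
  cmap <- setNames(cl$cluster, cl$chain)
  want <- character(0)
  for (i in 1:6) for (j in 1:6) {
    pi <- paste0("P", i); pj <- paste0("P", j)
    chi <- pc$chain[pc$protein_id == pi]; chj <- pc$chain[pc$protein_id == pj]
    hit <- FALSE
    for (k in seq_len(nrow(ct))) {
      if (ct$n_interface[k] > 5) {
        ka <- cmap[ct$chain_a[k]]; kb <- cmap[ct$chain_b[k]]
        if ((any(cmap[chi] == ka) && any(cmap[chj] == kb)) ||
            (any(cmap[chi] == kb) && any(cmap[chj] == ka))) hit <- TRUE
      }
    }
    if (hit) want <- c(want, paste(min(pi, pj), max(pi, pj)))
  }
  expect_setequal(paste(got$a, got$b), unique(want))
})

test_that("extending the positives cannot lower the enrichment at fixed predictions", {
  ids <- paste0("p", 1:6)
  df <- tidyr::expand_grid(receptor = ids, ligand = ids)
  df <- df[df$receptor != df$ligand, ]
  set.seed(13)
  df$nii_scaled <- runif(nrow(df))
  pos1 <- tibble::tibble(a = "p1", b = "p2")
  pos2 <- dplyr::bind_rows(pos1, tibble::tibble(a = c("p3", "p5"), b = c("p4", "p6")))
  for (x in c(20, 40, 60)) {
    pr1 <- partner_ranks(df, pos1)
    pr2 <- partner_ranks(df, pos2)
    p1 <- ptopx(ifelse(is.na(pr1$best_rank), pr1$n_candidates, pr1$best_rank), x, pr1$n_candidates)
    p2 <- ptopx(ifelse(is.na(pr2$best_rank), pr2$n_candidates, pr2$best_rank), x, pr2$n_candidates)
    expect_gte(p2, p1)
  }
})
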