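test_that("circular variance hits its geometric extremes and matches the formula", {
  # all neighbours in one direction -> CV = 0
  line <- bead_protein("line", rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(9, 0, 0)))
  cv <- circular_variance(line, radius = 20)
  expect_equal(cv[1], 0)
  # neighbours at +-x, +-y, +-z -> vector sum zero -> CV = 1
  oct <- bead_protein("oct", rbind(c(0, 0, 0), c(4, 0, 0), c(-4, 0, 0),
                                   c(0, 4, 0), c(0, -4, 0), c(0, 0, 4), c(0, 0, -4)))
  expect_equal(circular_variance(oct, radius = 10)[1], 1)
  # random cloud: independent recomputation of the definition
  set.seed(12)
  pts <- matrix(rnorm(45, sd = 3), 15)
  p <- bead_protein("cloud", pts)
  cv <- circular_variance(p, radius = 12)
  for (i in c(1, 7, 15)) {
    v <- sweep(pts[-i, , drop = FALSE], 2, pts[i, ])
    d <- sqrt(rowSums(v^2))
    sel <- d <= 12
    u <- v[sel, , drop = FALSE] / d[sel]
    expect_equal(cv[i], 1 - sqrt(sum(colSums(u)^2)) / sum(sel))
  }
  # isolated residue: CV = 0 with a warning
  expect_warning(cv0 <- circular_variance(bead_protein("iso", rbind(c(0, 0, 0), c(100, 0, 0))), 12))
  expect_equal(cv0, c(0, 0))
})

test_that("docking-inferred propensities equal hand counts on a constructed store", {
  spec <- fixture_spec(seed = 21, n_proteins = 4, n_residues = 20, patch_size = 4)
  st <- make_scored_store(spec, n_conformations = 6)
  id <- names(st$proteins)[1]
  got <- nip_from_docking(st, id, top_k = 3)
  # hand count: membership of each residue among the top-3 poses per partner
  counts <- numeric(nrow(st$proteins[[id]]$residues))
  poses <- st$poses
  for (p in unique(poses$ligand_id[poses$receptor_id == id])) {
    sub <- poses[poses$receptor_id == id & poses$ligand_id == p, ]
    sub <- sub[order(sub$e_maxdo), ][1:3, ]
    for (s in sub$di_receptor) counts[s + 1] <- counts[s + 1] + 1
  }
  for (p in setdiff(unique(poses$receptor_id[poses$ligand_id == id]), id)) {
    sub <- poses[poses$ligand_id == id & poses$receptor_id == p, ]
    sub <- sub[order(sub$e_maxdo), ][1:3, ]
    for (s in sub$di_ligand) counts[s + 1] <- counts[s + 1] + 1
  }
  expect_equal(got, counts / max(counts))
  expect_equal(max(got), 1)
  expect_true(all(got >= 0 & got <= 1))
  expect_error(nip_from_docking(st, "nope"), "absent")
})

test_that("all four descriptors live in [0,1] on the surface", {
  toy <- make_toy_surface(interface_size = 8, n_residues = 40, seed = 4)
  nip <- runif(40)
  desc <- descriptor_table(toy$protein, nip = nip)
  for (col in c("tjet", "pc", "cv", "nip")) {
    expect_true(all(desc[[col]] >= 0 & desc[[col]] <= 1), info = col)
  }
  expect_equal(nrow(desc), 40)
})

test_that("strategy families have the documented scheme counts and seed rules", {
  expect_length(strategy_config("SC-juxt")$schemes, 4)
  expect_length(strategy_config("SC-mix")$schemes, 3)
  expect_length(strategy_config("SC-monoSeed-mix")$schemes, 3)
  sd <- strategy_config("SC-dockSeed-mix")
  expect_length(sd$schemes, 3)
  for (sc in sd$schemes) {
    expect_equal(sc$seed, "nip")           # seeds from docking propensities only
    expect_true("nip" %in% sc$extend)      # growth mixes NIP back in
  }
  for (sc in strategy_config("SC-monoSeed-mix")$schemes) {
    expect_false("nip" %in% sc$seed)
    expect_true("nip" %in% sc$extend)
  }
  juxt_names <- vapply(strategy_config("SC-juxt")$schemes, `[[`, character(1), "name")
  expect_setequal(juxt_names, c("SC_cons", "SC_notLig", "SC_geom", "SC_NIP"))
})

test_that("a separable signal is recovered as the patch by every scheme", {
  toy <- make_toy_surface(interface_size = 8, n_residues = 50, seed = 6)
  cluster <- toy$interface$residues
  desc <- descriptor_table(toy$protein)
  ideal <- as.numeric(desc$res_idx %in% cluster)
  desc$tjet <- ideal; desc$pc <- ideal; desc$nip <- ideal
  desc$cv <- 1 - ideal  # protruding (low CV) on the cluster
  for (family in c("SC-juxt", "SC-mix", "SC-monoSeed-mix", "SC-dockSeed-mix")) {
    for (scheme in strategy_config(family)$schemes) {
      set.seed(1)
      patch <- grow_patch(desc, scheme, toy$graph)
      expect_equal(patch, cluster, info = paste(family, scheme$name))
    }
  }
})

test_that("seed-stage selection matches an independent percentile-rule oracle", {
  toy <- make_toy_surface(interface_size = 8, n_residues = 60, seed = 8)
  set.seed(3)
  desc <- descriptor_table(toy$protein, nip = runif(60))
  scheme <- list(name = "nip-only", seed = "nip", extend = "nip", outer = "nip")
  # oracle: residues at/above the 85th percentile of NIP, connected component
  # containing the picked cluster must be among those components
  thr <- quantile(desc$nip, 0.85, names = FALSE)
  eligible <- desc$res_idx[desc$nip >= thr & desc$nip > 0]
  comps <- dockmate:::graph_components(toy$graph, eligible)
  set.seed(9)
  patch <- grow_patch(desc, scheme, toy$graph,
                      thresholds = c(seed = 0.15, extend = 0.30, outer = 0.40),
                      max_rounds = 0)
  expect_true(any(vapply(comps, function(cl) setequal(cl, patch), logical(1))))
})

test_that("a dockSeed scheme with zero propensities yields an empty patch with warning", {
  toy <- make_toy_surface(interface_size = 6, n_residues = 30, seed = 5)
  desc <- descriptor_table(toy$protein)  # nip defaults to all zero
  scheme <- strategy_config("SC-dockSeed-mix")$schemes[[1]]
  expect_warning(patch <- grow_patch(desc, scheme, toy$graph), "no seed")
  expect_length(patch, 0)
})

test_that("consensus keeps residues seen in at least 2 of 10 runs and is seeded", {
  toy <- make_toy_surface(interface_size = 8, n_residues = 50, seed = 6)
  cluster <- toy$interface$residues
  desc <- descriptor_table(toy$protein)
  ideal <- as.numeric(desc$res_idx %in% cluster)
  desc$tjet <- ideal; desc$pc <- ideal; desc$nip <- ideal; desc$cv <- 1 - ideal
  strat <- strategy_config("SC-dockSeed-mix")
  pred <- consensus_patches(desc, strat, toy$graph, seed = 2)
  # deterministic field: every run identical, consensus = the designed cluster
  expect_length(pred$patches, length(strat$schemes))
  for (p in pred$patches) {
    expect_equal(p$residues, cluster)
    expect_true(all(p$votes >= 2))
  }
  pred2 <- consensus_patches(desc, strat, toy$graph, seed = 2)
  expect_identical(lapply(pred$patches, `[[`, "residues"),
                   lapply(pred2$patches, `[[`, "residues"))
  # raising the vote threshold can only shrink the consensus
  strat10 <- strat; strat10$min_votes <- 10
  pred10 <- consensus_patches(desc, strat10, toy$graph, seed = 2)
  expect_lte(length(unique(unlist(lapply(pred10$patches, `[[`, "residues")))),
             length(unique(unlist(lapply(pred$patches, `[[`, "residues")))))
})

test_that("oracle selection maximises F1 over patch unions; blind takes the union", {
  mkpred <- function(sets) {
    structure(list(protein_id = "x",
                   patches = lapply(sets, function(s) list(residues = s, votes = NULL)),
                   family = "SC-juxt", seed = 1),
              class = "patch_prediction")
  }
  known <- new_interface("x", 0:9, "experimental")
  # F1(A) < F1(B) < F1(A u B): the union must win
  A <- 0:3                      # ppv 1, sens 0.4
  B <- c(4:9, 20L)              # ppv 6/7, sens 0.6
  pred <- mkpred(list(A, B))
  sel <- select_reference_interface(pred, "oracle", known)
  expect_equal(sel$residues, sort(union(A, B)))
  # exhaustive-enumeration oracle over all subsets agrees
  f1 <- function(s) interface_agreement(s, known)$f1
  best <- which.max(c(f1(A), f1(B), f1(union(A, B))))
  expect_equal(best, 3L)
  # oracle selection is at least as good as any single patch (by construction)
  expect_gte(attr(sel, "f1"), max(f1(A), f1(B)))
  # a single patch equal to the known interface is returned with F1 = 1
  perfect <- select_reference_interface(mkpred(list(0:9, c(30L, 31L))), "oracle", known)
  expect_equal(perfect$residues, 0:9)
  expect_equal(attr(perfect, "f1"), 1)
  # blind mode: union of consensus patches
  blind <- select_reference_interface(pred, "blind")
  expect_equal(blind$residues, sort(union(A, B)))
  expect_equal(blind$provenance, "predicted")
  # no patches: empty interface with warning
  expect_warning(none <- select_reference_interface(mkpred(list()), "blind"), "no predicted")
  expect_length(none$residues, 0)
})

test_that("dockSeed strategy recovers a designed interface from NIP signal", {
  # NIP peaks on the designed cognate patch; conservation/propensity are flat
  toy <- make_toy_surface(interface_size = 8, n_residues = 50, seed = 14)
  cluster <- toy$interface$residues
  set.seed(2)
  nip <- runif(50, 0, 0.3)
  nip[cluster + 1] <- runif(8, 0.85, 1)
  desc <- descriptor_table(toy$protein, nip = nip)
  pred <- consensus_patches(desc, strategy_config("SC-dockSeed-mix"), toy$graph, seed = 3)
  sel <- select_reference_interface(pred, "oracle", toy$interface)
  expect_gte(interface_agreement(sel, toy$interface)$f1, 0.8)
})
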