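#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the proteins, the scoring
#' hyper-parameters (docked-interface distance, patch strategy, energy,
#' pair potential — the default values are the recommended ones: d = 5
#' \eqn{\mathrm{\AA}}, SC-dockSeed-mix, the 8-6 docking energy, pair
#' potential on), the docking settings, the reference-interface source and
#' the output directory.
#'
#' @param proteins Named list of `cg_protein` objects, or a manifest data
#'   frame with columns `protein_id`, `path` (PDB files), optional `chains`
#'   (comma-separated) and `class`.
#' @param params List of scoring parameters: `d`, `strategy`, `energy`,
#'   `pp` (logical), `pp_mode`.
#' @param dock A [dock_settings()] object.
#' @param ri_source `"predicted"`, `"experimental"` or `"designed"` (the
#'   latter two require `ris`).
#' @param ris Named list of reference interfaces (for non-predicted sources).
#' @param potential Optional `contact_potential` for pair-potential scoring
#'   (when absent and `pp` is on, planted/ingested `pp` columns are
#'   expected).
#' @param classes Named protein id -> class vector (from the manifest when
#'   given there).
#' @param positives Optional known-pair data frame for evaluation.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @param seed Run seed (overrides the dock settings seed).
#' @param resume Reuse stage outputs already on disk when the configuration
#'   hash matches.
#' @return A `run_config` list with a content hash.
#' @export
run_config <- function(proteins,
                       params = list(d = 5, strategy = "SC-dockSeed-mix",
                                     energy = "maxdo", pp = TRUE, pp_mode = "factor"),
                       dock = dock_settings(n_positions = 24, n_rotations = 6),
                       ri_source = c("predicted", "experimental", "designed"),
                       ris = NULL, potential = NULL, classes = NULL,
                       positives = NULL, out_dir = NULL, seed = NULL,
                       resume = FALSE) {
  ri_source <- match.arg(ri_source)
  if (is.data.frame(proteins)) {
    manifest <- tibble::as_tibble(proteins)
    missing_files <- manifest$path[!file.exists(manifest$path)]
    if (length(missing_files)) stop("manifest file(s) not found: ", paste(missing_files, collapse = ", "))
    if (is.null(classes) && "class" %in% names(manifest)) {
      classes <- stats::setNames(manifest$class, manifest$protein_id)
    }
    loaded <- lapply(seq_len(nrow(manifest)), function(i) {
      chains <- if ("chains" %in% names(manifest) && !is.na(manifest$chains[i])) {
        strsplit(manifest$chains[i], ",")[[1]]
      } else NULL
      coarse_grain(read_structure(manifest$path[i], chains, manifest$protein_id[i]))
    })
    proteins <- stats::setNames(loaded, manifest$protein_id)
  } else {
    proteins <- name_proteins(proteins)
  }
  if (!is.null(seed)) dock$seed <- as.integer(seed)
  defaults <- list(d = 5, strategy = "SC-dockSeed-mix", energy = "maxdo",
                   pp = TRUE, pp_mode = "factor")
  params <- utils::modifyList(defaults, params)
  if (ri_source != "predicted" && is.null(ris)) {
    stop("ri_source = ", ri_source, " requires reference interfaces in `ris`")
  }
  cfg <- list(params = params, dock = unclass(dock), ri_source = ri_source,
              protein_ids = names(proteins))
  structure(list(proteins = proteins, params = params, dock = dock,
                 ri_source = ri_source, ris = ris, potential = potential,
                 classes = classes, positives = positives,
                 out_dir = out_dir, resume = resume,
                 hash = rlang::hash(cfg)),
            class = "run_config")
}

#' Run the full partner-identification pipeline
#'
#' Cross-docks the set, annotates docked interfaces, obtains reference
#' interfaces (predicted patches or supplied ones), scores every ordered
#' pair into an interaction matrix, and evaluates partner discrimination
#' when known pairs are supplied. Each stage writes its output (text
#' formats) under the configured directory together with the configuration
#' hash, and with `resume = TRUE` finished stages are reloaded instead of
#' recomputed.
#'
#' @param config A [run_config()].
#' @return List with `store`, `ris`, `scores` (`interaction_table`),
#'   `evaluation` (AUC/enrichment or `NULL`), `config`, and per-stage
#'   `log` counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  log <- list()
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    hash_file <- file.path(out, "config_hash.txt")
    if (config$resume && file.exists(hash_file) &&
        !identical(readLines(hash_file)[1], config$hash)) {
      stop("output directory holds results of a different configuration; refusing to resume")
    }
    writeLines(c(config$hash, paste("seed", config$dock$seed),
                 paste("package", as.character(utils::packageVersion("dockmate")))),
               hash_file)
  }
  # stage 1: cross-docking
  store_dir <- if (!is.null(out)) file.path(out, "store") else NULL
  if (config$resume && !is.null(store_dir) && file.exists(file.path(store_dir, "poses.tsv"))) {
    store <- read_store(store_dir)
    store$proteins <- config$proteins
  } else {
    store <- cross_dock(config$proteins, config$dock)
    store <- docked_interfaces(store, config$params$d)
    if (!is.null(store_dir)) write_store(store, store_dir)
  }
  log$poses <- nrow(store$poses)
  # stage 2: reference interfaces
  if (config$ri_source == "predicted") {
    ris <- predict_all_ris(store, config)
  } else {
    ris <- config$ris
  }
  if (!is.null(out)) {
    write_interface_table(unname(ris), file.path(out, "reference_interfaces.tsv"),
                          proteins = config$proteins)
  }
  log$ri_sizes <- vapply(ris, function(x) length(iface_residues(x)), integer(1))
  # stage 3: pair potential
  use_pp <- isTRUE(config$params$pp)
  if (use_pp && !is.null(config$potential)) store <- add_pp_scores(store, config$potential)
  if (use_pp && !"pp" %in% names(store$poses)) {
    warning("pair potential requested but no scores available; continuing without it")
    use_pp <- FALSE
  }
  # stage 4: interaction matrix
  ii_tbl <- score_pairs(store, ris, energy = config$params$energy,
                        use_pp = use_pp, pp_mode = config$params$pp_mode,
                        d = config$params$d)
  scores <- interaction_table(ii_tbl)
  if (!is.null(out)) write_interaction_table(scores, file.path(out, "interaction_matrix.tsv"))
  log$favourable_pairs <- sum(scores$ii < 0)
  # stage 5: evaluation
  evaluation <- NULL
  if (!is.null(config$positives)) {
    evaluation <- list(
      auc = auc_partner(scores, config$positives),
      ptopx = ptopx_curve(scores, config$positives)
    )
    if (!is.null(config$classes)) {
      evaluation$auc_within_class <- tryCatch(
        auc_partner(scores, config$positives, scope = "within-class",
                    classes = config$classes),
        error = function(e) NA_real_)
    }
    if (!is.null(out)) {
      jsonlite::write_json(list(auc = evaluation$auc,
                                ptopx = evaluation$ptopx),
                           file.path(out, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(store = store, ris = ris, scores = scores, evaluation = evaluation,
       config = config, log = log)
}

predict_all_ris <- function(store, config) {
  strategy <- strategy_config(config$params$strategy)
  ris <- list()
  for (id in names(config$proteins)) {
    p <- config$proteins[[id]]
    graph <- surface_graph(p, d = 5)
    nip <- nip_from_docking(store, id)
    desc <- descriptor_table(p, nip = nip)
    pred <- consensus_patches(desc, strategy, graph, seed = config$dock$seed)
    known <- if (!is.null(config$ris)) config$ris[[id]] else NULL
    mode <- if (is.null(known)) "blind" else "oracle"
    ris[[id]] <- select_reference_interface(pred, mode, known)
  }
  ris
}
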