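#' Pipeline configuration
#'
#' Gathers every tunable of the analysis -> model -> design -> score chain.
#' Input is either a synthetic complex recipe (`synthetic`) or file paths to a
#' trajectory + topology; referenced files are checked at validation time,
#' before any stage runs.
#'
#' @param synthetic Optional [synthetic_spec()]; when given, the complex and
#'   trajectory are generated.
#' @param trajectory_path,structure_path,topology_path Input files (multi-model
#'   PDB trajectory, complex PDB, topology TSV) when `synthetic` is `NULL`.
#' @param window_fraction Fraction of the trajectory tail analyzed.
#' @param n_clusters Cluster count for the receptor ensemble.
#' @param cluster_stride Frame stride for the pairwise RMSD matrix.
#' @param key_threshold Key-residue contribution threshold, kcal/mol.
#' @param stable_occupancy Stable H-bond occupancy threshold, percent.
#' @param shortlist_threshold Docking-score shortlist cutoff, kcal/mol.
#' @param per_region Groups kept per region in selection.
#' @param params A [gb_params()].
#' @param library_path Design library YAML (`NULL` = packaged default).
#' @param scorer `"surrogate"` or `"table:<path>"`.
#' @param entropy Optional external `T_delta_S`, kcal/mol.
#' @param seed Integer seed.
#' @return A `bs_pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, trajectory_path = NULL,
                            structure_path = NULL, topology_path = NULL,
                            window_fraction = 0.2, n_clusters = 2L,
                            cluster_stride = 1L, key_threshold = 0.5,
                            stable_occupancy = 50, shortlist_threshold = -10.0,
                            per_region = 3L, params = gb_params(),
                            library_path = NULL, scorer = "surrogate",
                            entropy = NULL, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "bs_pipeline_config")
  if (is.null(synthetic)) {
    for (p in c(trajectory_path, structure_path, topology_path)) {
      if (is.null(p) || !file.exists(p)) {
        abort(paste0("pipeline input missing or not found: ",
                     if (is.null(p)) "(NULL)" else p))
      }
    }
  }
  if (!is.null(library_path) && !file.exists(library_path)) {
    abort(paste0("design library not found: ", library_path))
  }
  if (grepl("^table:", scorer) && !file.exists(sub("^table:", "", scorer))) {
    abort(paste0("score table not found: ", sub("^table:", "", scorer)))
  }
  if (window_fraction <= 0 || window_fraction > 1) abort("window_fraction in (0,1]")
  cfg
}

#' Run the full analysis -> model -> design -> score pipeline
#'
#' Executes six stages (trajectory analysis, MM/GBSA, per-residue
#' decomposition + binding model, design enumeration, combination, ensemble
#' scoring) and writes every stage output as TSV into `out_dir`, together with
#' a machine-readable JSON manifest and a plain-text log. Identical config and
#' seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; default: a timestamped directory
#'   under `tempdir()`).
#' @return The manifest as a list (invisibly contains `out_dir`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "bs_pipeline_config"))
  out_dir <- out_dir %||% file.path(tempdir(),
                                    format(Sys.time(), "bindsight_run_%Y%m%d_%H%M%S"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(paste0("[", ...,"]\n"), file = log_path, append = TRUE, sep = "")
  }
  outputs <- list()
  stage <- function(name, fun) {
    logf("stage ", name, " start")
    res <- tryCatch(fun(), error = function(e) {
      logf("stage ", name, " FAILED: ", conditionMessage(e))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    logf("stage ", name, " done")
    res
  }

  # -- inputs -----------------------------------------------------------
  inp <- stage("input", function() {
    if (!is.null(config$synthetic)) {
      st <- generate_complex(config$synthetic)
      traj <- generate_trajectory(st, config$synthetic)
    } else {
      st <- read_structure(config$structure_path, config$topology_path)
      traj <- read_trajectory(config$trajectory_path, st)
    }
    list(st = st, traj = traj)
  })
  st <- inp$st; traj <- inp$traj
  win <- last_fraction_window(traj, config$window_fraction)
  wtraj <- select_window(traj, win)

  # -- 1: trajectory analysis ------------------------------------------
  an <- stage("analysis", function() {
    rmsd <- rmsd_series(traj, "receptor")
    rmsf <- rmsf_per_residue(traj, "receptor")
    hb <- detect_hbonds(wtraj)
    hbc <- hbond_count_series(wtraj)
    cl <- cluster_frames(wtraj, "receptor", config$n_clusters,
                         config$cluster_stride)
    f1 <- file.path(out_dir, "rmsd.tsv")
    write_table(rmsd, f1, sort_by = "frame")
    f2 <- file.path(out_dir, "rmsf.tsv")
    write_table(rmsf, f2, sort_by = c("chain_id", "residue_index"))
    f3 <- file.path(out_dir, "hbond_occupancy.tsv")
    write_table(select(hb, -"flags"), f3)
    f4 <- file.path(out_dir, "cluster_populations.tsv")
    write_table(cl$clusters, f4, sort_by = "cluster")
    outputs[["analysis"]] <<- c(f1, f2, f3, f4)
    list(hb = hb, cl = cl, hbc = hbc)
  })

  # -- 2: MM/GBSA -------------------------------------------------------
  be <- stage("mmgbsa", function() {
    be <- average_binding_energy(wtraj, params = config$params,
                                 entropy = config$entropy)
    f <- file.path(out_dir, "binding_energy.tsv")
    write_table(tidy(be), f)
    outputs[["mmgbsa"]] <<- f
    be
  })

  # -- 3: decomposition + binding model --------------------------------
  model <- stage("report", function() {
    dec <- decompose_per_residue(wtraj, params = config$params,
                                 key_threshold = config$key_threshold)
    f1 <- file.path(out_dir, "residue_decomposition.tsv")
    write_table(dec, f1, sort_by = c("chain_id", "residue_index"))
    bm <- classify_interactions(dec, an$hb,
                                thresholds = list(
                                  key_threshold = config$key_threshold,
                                  stable_occupancy = config$stable_occupancy))
    f2 <- file.path(out_dir, "binding_model.tsv")
    write_table(bm$residue_classes, f2, sort_by = "residue_index")
    outputs[["report"]] <<- c(f1, f2)
    bm
  })

  # -- 4: design enumeration -------------------------------------------
  lib <- read_design_library(config$library_path)
  one <- stage("design_one_region", function() {
    one <- enumerate_one_region(lib$scaffold, lib$one_region)
    f <- file.path(out_dir, "one_region_library.tsv")
    write_table(select(one, -"smiles_raw"), f, sort_by = "name")
    outputs[["design_one_region"]] <<- f
    one
  })

  # -- 5: combination ---------------------------------------------------
  comb <- stage("design_combination", function() {
    comb <- combine_regions(lib$scaffold, lib$combination)
    f1 <- file.path(out_dir, "combination_library.tsv")
    write_table(select(comb, -"choice", -"smiles_raw"), f1, sort_by = "name")
    f2 <- file.path(out_dir, "combination_library.smi")
    writeLines(paste(comb$name, comb$smiles, sep = "\t"), f2)
    outputs[["design_combination"]] <<- c(f1, f2)
    comb
  })

  # -- 6: ensemble scoring ---------------------------------------------
  ranked <- stage("score", function() {
    ens <- receptor_ensemble(wtraj, an$cl)
    scr <- if (grepl("^table:", config$scorer)) {
      load_score_table(sub("^table:", "", config$scorer))
    } else {
      surrogate_scorer(default_pose = st, params = config$params)
    }
    scored <- score_compounds(comb, ens, scr)
    ranked <- rank_and_shortlist(scored, config$shortlist_threshold)
    f <- file.path(out_dir, "ranked_compounds.tsv")
    write_table(ranked, f)
    outputs[["score"]] <<- f
    ranked
  })

  manifest <- list(
    package = "bindsight",
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_frames = n_frames(traj),
    n_frames_window = n_frames(wtraj),
    delta_G = be$delta_G,
    n_shortlisted = sum(ranked$shortlisted),
    stages = outputs,
    out_dir = out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("pipeline complete")
  invisible(manifest)
}

#' Compare candidate binding free energies
#'
#' Tabulates candidate binding free energies against a reference value (e.g.
#' the experimental affinity of the parent inhibitor) and all pairwise
#' differences.
#'
#' @param energies Tibble with `name` and `delta_G` (kcal/mol), one row per
#'   candidate.
#' @param reference Reference binding free energy, kcal/mol.
#' @return Tibble with `name`, `delta_G`, `vs_reference` (candidate minus
#'   reference); pairwise differences (`name_a`, `name_b`,
#'   `difference` = `delta_G_a - delta_G_b`) attached as attribute
#'   `"pairwise"`.
#' @export
compare_candidates <- function(energies, reference) {
  if (!nrow(energies)) abort("need at least one candidate")
  out <- energies |>
    mutate(vs_reference = .data$delta_G - reference)
  pw <- tidyr::expand_grid(a = seq_len(nrow(energies)), b = seq_len(nrow(energies))) |>
    filter(.data$a < .data$b) |>
    mutate(name_a = energies$name[.data$a], name_b = energies$name[.data$b],
           difference = energies$delta_G[.data$a] - energies$delta_G[.data$b]) |>
    select("name_a", "name_b", "difference")
  attr(out, "pairwise") <- pw
  out
}
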