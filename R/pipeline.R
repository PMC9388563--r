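# Single entry point chaining the stages (simulate -> phenotype ->
# density -> spatial -> signature -> predict -> survive -> stats) from
# one declarative YAML config. Stages communicate through files in the
# output directory; a versioned manifest records the config hash, seed
# and md5 of every output so identical inputs are checkable for
# byte-identical reruns.

.PIPELINE_STAGES <- c("simulate", "phenotype", "density", "spatial",
                      "signature", "predict", "survive", "stats")

#' Default pipeline configuration
#'
#' Every design default is explicit in the shipped config so deviations
#' are visible diffs: pairing radii 10/20/30 um, 20 um effective-density
#' and signature radius, 3 CV folds, 5000 repetitions (200 in fast mode),
#' the two-thirds density split, median prognostic-score cut.
#'
#' @return Nested named list, class `tiic_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(n_patients = 20L,
                    rois_per_patient = list(TC = 4L, IM = 1L, N = 1L),
                    clustering = "thomas"),
    density = list(roi_classes = "TC", compartments = "all",
                   phenotypes = "signature"),
    spatial = list(radii_um = c(10, 20, 30), density_radius_um = 20,
                   roi_class = "TC"),
    signature = list(radius_um = 20, combined = FALSE),
    predict = list(families = classifier_families(), folds = 3L,
                   repetitions = 5000L, fast_repetitions = 200L,
                   grid = "default"),
    survive = list(endpoints = c("irpfs", "iros"), cut = "median"),
    stats = list(tertile_split = TRUE)),
    class = "tiic_config")
}

#' Read / write / validate a pipeline config
#'
#' @param path YAML file.
#' @return `read_config()` returns a validated `tiic_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(modifyList(unclass(default_config()), cfg))
}

#' @rdname read_config
#' @param config a `tiic_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_config
#' @export
validate_config <- function(config) {
  fail <- function(field, msg) stop("config field '", field, "': ", msg,
                                    call. = FALSE)
  if (!is.numeric(config$seed)) fail("seed", "must be an integer")
  if (!is.numeric(config$simulate$n_patients) ||
      config$simulate$n_patients < 1)
    fail("simulate.n_patients", "must be a positive integer")
  if (!all(config$spatial$radii_um > 0))
    fail("spatial.radii_um", "radii must be positive")
  if (!config$signature$radius_um %in% config$spatial$radii_um)
    fail("signature.radius_um", "must be one of spatial.radii_um")
  bad <- setdiff(config$predict$families, classifier_families())
  if (length(bad)) fail("predict.families",
                        paste("unknown:", paste(bad, collapse = ", ")))
  if (!all(config$survive$endpoints %in% c("os", "iros", "irpfs")))
    fail("survive.endpoints", "must be os/iros/irpfs")
  structure(config, class = "tiic_config")
}

.stage_paths <- function(out_dir) {
  list(cells = file.path(out_dir, "cells.csv"),
       clinical = file.path(out_dir, "clinical.csv"),
       phenotype = file.path(out_dir, "phenotype_counts.csv"),
       density = file.path(out_dir, "density.csv"),
       spatial = file.path(out_dir, "spatial.csv"),
       signature = file.path(out_dir, "signature.csv"),
       predict = file.path(out_dir, "model_reports.json"),
       survive = file.path(out_dir, "survival.json"),
       stats = file.path(out_dir, "stats.json"),
       manifest = file.path(out_dir, "manifest.json"))
}

.need <- function(path, stage)
  if (!file.exists(path))
    stop("missing upstream output '", basename(path),
         "'; run stage '", stage, "' first", call. = FALSE)

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on one output
#' directory. Upstream outputs already on disk are reused; a missing
#' upstream output names the stage to run. Writes `manifest.json` with
#' the config hash, seed, package version and md5 of every output.
#'
#' @param config a `tiic_config` (or path to a YAML config).
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages, or `"all"`.
#' @param fast use the fast repetition count and default parameters in
#'   the predict stage.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = "all", fast = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  if (identical(stages, "all")) stages <- .PIPELINE_STAGES
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(.PIPELINE_STAGES, collapse = ", "),
         call. = FALSE)
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- .stage_paths(out_dir)
  reg <- default_registry()
  sf <- signature_features()

  cfg_file <- file.path(out_dir, "config_used.yaml")
  write_config(config, cfg_file)

  load_data <- function() {
    .need(paths$cells, "simulate")
    read_cell_table(paths$cells)
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        sim_args <- config$simulate
        sim_args$rois_per_patient <- unlist(sim_args$rois_per_patient)
        sim_args$seed <- config$seed
        study <- do.call(simulation_config, sim_args)
        study <- simulate_cohort(study)
        write_cell_table(study$data, paths$cells)
        data.table::fwrite(study$clinical[,
          setdiff(names(study$clinical), "responder")],
          paths$clinical, na = "")
      },
      phenotype = {
        data <- load_data()
        hits <- assign_phenotypes(data$cells, reg)
        counts <- aggregate(hits,
                            by = list(patient_id = data$cells$patient_id,
                                      roi_class = data$cells$roi_class),
                            FUN = sum)
        data.table::fwrite(counts, paths$phenotype)
      },
      density = {
        data <- load_data()
        ph <- config$density$phenotypes
        if (identical(ph, "signature"))
          ph <- sf$phenotype[sf$kind == "density"]
        dt <- density_table(data, reg, phenotypes = ph,
                            roi_classes = config$density$roi_classes,
                            compartments = config$density$compartments)
        data.table::fwrite(dt, paths$density)
      },
      spatial = {
        data <- load_data()
        st <- spatial_table(data, reg,
                            phenotypes = sf$phenotype[sf$kind ==
                                                        "effective_score"],
                            radii_um = config$spatial$radii_um,
                            density_radius_um =
                              config$spatial$density_radius_um,
                            roi_class = config$spatial$roi_class)
        data.table::fwrite(st, paths$spatial, na = "")
      },
      signature = {
        .need(paths$density, "density"); .need(paths$spatial, "spatial")
        dt <- as.data.frame(data.table::fread(paths$density))
        st <- as.data.frame(data.table::fread(paths$spatial,
                                              na.strings = ""))
        clin <- if (config$signature$combined) {
          .need(paths$clinical, "simulate")
          read_clinical_table(paths$clinical)
        }
        sig <- build_signature(dt, st, clinical = clin,
                               combined = config$signature$combined,
                               radius_um = config$signature$radius_um)
        write_features(sig, paths$signature)
      },
      predict = {
        .need(paths$signature, "signature")
        .need(paths$clinical, "simulate")
        sig <- read_features(paths$signature)
        clin <- read_clinical_table(paths$clinical)
        y <- clin$responder[match(sig$patient_id, clin$patient_id)]
        Xc <- setdiff(names(sig), c("patient_id", "complete"))
        reps <- if (fast) config$predict$fast_repetitions else
          config$predict$repetitions
        grid <- if (fast) NULL else config$predict$grid
        reports <- lapply(config$predict$families, function(fam) {
          r <- fit_predict_cv(as.matrix(sig[, Xc]), y, fam,
                              param_grid = grid, repetitions = reps,
                              seed = config$seed,
                              n_folds = config$predict$folds)
          r[c("family", "mean_auc", "ci95", "auc_per_repetition",
              "chosen_params", "importances", "n_dropped")]
        })
        names(reports) <- config$predict$families
        jsonlite::write_json(reports, paths$predict, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
      },
      survive = {
        .need(paths$signature, "signature")
        .need(paths$clinical, "simulate")
        sig <- read_features(paths$signature)
        clin <- read_clinical_table(paths$clinical)
        res <- lapply(config$survive$endpoints, function(ep) {
          sd_ <- data.frame(
            patient_id = clin$patient_id,
            time = clin[[paste0(ep, "_months")]],
            event = clin[[paste0(ep, "_event")]])
          ps <- prognostic_score(sig, sd_, cut = config$survive$cut)
          idx <- match(ps$scores$patient_id, sd_$patient_id)
          lr <- logrank_test(sd_$time[idx], sd_$event[idx],
                             ps$scores$group)
          list(endpoint = ep, weights = as.list(ps$weights),
               cut = ps$cut_value,
               n_high = sum(ps$scores$group == "high"),
               n_low = sum(ps$scores$group == "low"),
               logrank_chisq = lr$statistic, logrank_p = lr$p)
        })
        names(res) <- config$survive$endpoints
        jsonlite::write_json(res, paths$survive, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
      },
      stats = {
        .need(paths$density, "density")
        .need(paths$clinical, "simulate")
        dt <- as.data.frame(data.table::fread(paths$density))
        clin <- read_clinical_table(paths$clinical)
        out <- list()
        if (isTRUE(config$stats$tertile_split)) {
          out$tertile_os_logrank <- lapply(
            split(dt, dt$phenotype), function(d) {
              grp <- dichotomise_tertile(
                setNames(d$density, d$patient_id))
              idx <- match(names(grp), clin$patient_id)
              lr <- logrank_test(clin$os_months[idx],
                                 clin$os_event[idx], grp)
              list(n_high = sum(grp == "high"),
                   n_low = sum(grp == "low"),
                   chisq = lr$statistic, p = lr$p)
            })
        }
        jsonlite::write_json(out, paths$stats, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
      })
  }

  outputs <- Filter(file.exists, paths[setdiff(names(paths), "manifest")])
  manifest <- list(
    package_version = as.character(packageVersion("tiicsig")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    stages = stages,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Command-line interface
#'
#' Entry point behind the `inst/cli/tiicsig.R` script. Subcommands are
#' the pipeline stages plus `run-all`; flags: `--config <yaml>`,
#' `--out <dir>`, `--seed <int>`, `--fast`.
#'
#' @param args character vector of CLI arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
tiic_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: tiicsig <stage>|run-all [--config file.yaml] [--out dir]",
    " [--seed n] [--fast]\n  stages: ",
    paste(.PIPELINE_STAGES, collapse = ", "))
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  stage <- args[1]
  if (!stage %in% c(.PIPELINE_STAGES, "run-all")) {
    message("unknown stage '", stage, "'\n", usage)
    return(invisible(1L))
  }
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  config <- if (!is.null(cf <- getopt("--config"))) read_config(cf) else
    default_config()
  if (!is.null(s <- getopt("--seed"))) config$seed <- as.integer(s)
  out_dir <- getopt("--out", "tiicsig_out")
  stages <- if (stage == "run-all") "all" else stage
  status <- tryCatch({
    run_pipeline(config, out_dir, stages, fast = "--fast" %in% args)
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
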