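#' Pipeline run configuration
#'
#' Bundles per-stage configuration, stage toggles and the global seed for
#' [run_pipeline()]. Stages consume each other's outputs in order:
#' `analyze` needs `generate`, `learning` and `decode` need `analyze`.
#'
#' @param seed global seed (mandatory; each stage derives its own stream
#'   from it).
#' @param preset species preset for the synthetic data.
#' @param stages character subset of
#'   `c("generate", "analyze", "circuit", "learning", "decode")`.
#' @param generator a [generator_config()] (defaults to the preset).
#' @param circuit_params a [circuit_params()].
#' @param noise a [noise_config()].
#' @param training a [training_config()].
#' @param pair_targets target correlations for the learning-stage similar
#'   and dissimilar synthetic pairs.
#' @param decoders decoders evaluated in the decode stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            preset = "fly",
                            stages = c("generate", "analyze", "circuit",
                                       "learning", "decode"),
                            generator = NULL,
                            circuit_params = olfstoch::circuit_params(),
                            noise = noise_config(),
                            training = training_config(simplified_saturation = TRUE),
                            pair_targets = c(similar = 0.6, dissimilar = 0.05),
                            decoders = c("lda", "knn", "svm")) {
  if (missing(seed)) stop("a seed is mandatory")
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(generator)) generator <- generator_config(preset)
  structure(list(seed = as.integer(seed), preset = preset, stages = stages,
                 generator = generator, circuit_params = circuit_params,
                 noise = noise, training = training,
                 pair_targets = pair_targets, decoders = decoders),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order: synthetic-data
#' generation, response statistics (significance, reliability classes,
#' population fractions, Gamma fits, overlap), a circuit-model run scored
#' against the stochastic-code characteristics, the learning-model
#' discrimination analysis on similar and dissimilar synthetic pairs, and
#' class-masked decoding. Tables are written as CSV and the headline
#' numbers as a JSON summary; every artifact records the configuration
#' hash and seed. A disabled stage leaves no outputs, and stages whose
#' inputs are missing refuse to run.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing). `NULL` skips all
#'   file output.
#' @param quiet suppress per-stage progress messages.
#' @return A list of class `pipeline_result` with one element per executed
#'   stage plus `summary` (the JSON-serialized list) and `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  seed <- config$seed
  say <- function(...) if (!quiet) message("[olfstoch] ", ...)
  t0 <- proc.time()[["elapsed"]]
  result <- list(config_hash = hash, seed = seed)
  summary <- list(config_hash = hash, seed = seed)
  log_lines <- character(0)
  stage_done <- function(name) {
    el <- round(proc.time()[["elapsed"]] - t0, 2)
    log_lines <<- c(log_lines, sprintf("%s done at %.2fs", name, el))
    say(name, " done (", el, "s elapsed)")
  }
  need <- function(stage, dep, have)
    if (!have) stop("stage `", stage, "` requires stage `", dep,
                    "` to be enabled")

  if ("generate" %in% config$stages) {
    result$tensor <- generate_responses(config$generator, seed = seed)
    stage_done("generate")
  }

  if ("analyze" %in% config$stages) {
    need("analyze", "generate", !is.null(result$tensor))
    mask <- detect_significant(result$tensor)
    tab <- classify_cells(mask)
    fr <- population_fractions(tab, mask)
    ov <- pairwise_overlap(tab)
    rel_fit <- fit_gamma(result$tensor$latent$p)
    amp_fit <- fit_gamma(result$tensor$latent$amp_base)
    result$analysis <- list(mask = mask, table = tab, fractions = fr,
                            overlap = ov, reliability_fit = rel_fit,
                            amplitude_fit = amp_fit)
    s <- fr$summary
    summary$fractions <- as.list(stats::setNames(
      100 * c(s$per_trial_mean, s$per_odor_mean),
      c(paste0(s$class, "_per_trial_pct"), paste0(s$class, "_per_odor_pct"))))
    summary$gamma_fits <- list(
      reliability = as.list(coef(rel_fit)),
      amplitude = as.list(coef(amp_fit)))
    stage_done("analyze")
  }

  if ("circuit" %in% config$stages) {
    circ <- build_circuit(config$circuit_params, seed = seed + 1L)
    panel <- odor_panel(6L, config$circuit_params$n_pn_types, seed = seed + 2L)
    circ <- calibrate_apl_gain(circ, panel, 0.08)
    act <- run_experiment(circ, panel, config$noise, 6L, seed = seed + 3L)
    ev <- evaluate_characteristics(act)
    result$circuit <- list(circuit = circ, activity = act, evaluation = ev)
    summary$circuit_characteristics <- as.list(ev$stats)
    summary$circuit_pass <- ev$pass
    stage_done("circuit")
  }

  if ("learning" %in% config$stages) {
    need("learning", "analyze", !is.null(result$analysis))
    result$learning <- list()
    summary$learning <- list()
    for (kind in names(config$pair_targets)) {
      pt <- generate_correlated_pair(config$generator,
                                     config$pair_targets[[kind]],
                                     seed = seed + 10L + match(kind, names(config$pair_targets)))
      pm <- detect_significant(pt)
      ptab <- classify_cells(pm)
      wn <- train_association(ptab, c(1, 2), config$training, "normal",
                              seed = seed + 20L)
      we <- train_association(ptab, c(1, 2), config$training, "extended",
                              seed = seed + 21L)
      rn <- discrimination_score(wn, ptab)
      re <- discrimination_score(we, ptab)
      contrib <- contribution_by_reliability(rn, re)
      result$learning[[kind]] <- list(table = ptab, normal = rn,
                                      extended = re, contribution = contrib)
      ur <- function(r) r$by_class$D_abs[r$by_class$class == "unreliable"]
      rl <- function(r) r$by_class$D_abs[r$by_class$class == "reliable"]
      summary$learning[[kind]] <- list(
        unreliable_normal = ur(rn), unreliable_extended = ur(re),
        reliable_normal = rl(rn), reliable_extended = rl(re))
    }
    stage_done("learning")
  }

  if ("decode" %in% config$stages) {
    need("decode", "analyze", !is.null(result$analysis))
    feats <- response_features(result$analysis$mask)
    tab <- result$analysis$table
    result$decoding <- list()
    summary$decoding <- list()
    for (dec in config$decoders) {
      for (cl in c("all", "reliable", "unreliable")) {
        fm <- mask_by_class(feats, tab, cl)
        pm <- kfold_evaluate(fm, dec, seed = seed + 30L)
        key <- paste(dec, cl, sep = "_")
        result$decoding[[key]] <- pm
        summary$decoding[[key]] <- list(accuracy = pm$accuracy,
                                        a2a_auc = a2a_auc(pm))
      }
    }
    stage_done("decode")
  }

  result$summary <- summary
  result$log <- log_lines

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      path <- file.path(out_dir, name)
      con <- file(path, "w")
      writeLines(paste0("# config_hash=", hash, " seed=", seed), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    if (!is.null(result$analysis)) {
      wcsv(as.data.frame(result$analysis$table), "reliability_table.csv")
      wcsv(result$analysis$fractions$summary, "population_fractions.csv")
      wcsv(result$analysis$overlap$per_cell, "overlap_per_cell.csv")
    }
    if (!is.null(result$learning))
      for (kind in names(result$learning))
        wcsv(result$learning[[kind]]$contribution,
             paste0("discrimination_", kind, ".csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$seed, ", config ", x$config_hash, "\n",
      sep = "")
  cat("  stages: ", paste(setdiff(names(x), c("config_hash", "seed",
                                              "summary", "log")),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load a response tensor from disk
#'
#' @param path file path.
#' @param format `"long-csv"` (the [write_tensor_csv()] layout). The HDF5
#'   and NWB layouts of the original recordings are recognised but not
#'   readable here, and raise an informative error.
#' @return A [response_tensor()].
#' @export
load_dataset <- function(path, format = c("long-csv", "hdf5", "nwb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    "long-csv" = read_tensor_csv(path),
    hdf5 = stop("HDF5 tensors are not supported in this build: ",
                "no HDF5 interface is available to the package. ",
                "Export the recording to the long CSV layout instead."),
    nwb = stop("NWB recordings are not supported in this build: ",
               "no NWB interface is available to the package. ",
               "Export the ROI fluorescence series to the long CSV ",
               "layout instead."))
}
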