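# Pipeline driver and reproducibility manifest: simulate -> train /
# gridsearch -> evaluate, configured from a JSON/YAML-style list, with
# every random draw derived from the manifest's master seed.

#' Serialize a fitted model to JSON
#'
#' Embeds the fitted network parameters, the split criteria and the
#' full configuration needed to reproduce the fit.
#'
#' @param fit a [ddehm()] object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "ddehm"))
  obj <- list(params = jsonlite::fromJSON(mlp_to_json(fit$params)),
              criteria = lapply(fit$criteria, as.list),
              seed = fit$seed,
              restarts = nrow(fit$multistart),
              best_restart = fit$best_restart,
              h = fit$h,
              control = unclass(fit$control))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' Restore fitted network parameters from a fit JSON
#' @param path file written by [write_fit()].
#' @return list with `params` ([mlp_params()]) and the stored metadata.
#' @export
read_fit <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$params <- mlp_from_json(jsonlite::toJSON(obj$params, auto_unbox = TRUE,
                                               digits = I(17)))
  obj
}

#' Run a configured pipeline
#'
#' Executes the configured stages (`simulate`, `train`, `gridsearch`,
#' `evaluate`) and writes a run manifest (configuration snapshot,
#' seeds, package version, input hashes, outputs) sufficient to
#' reproduce every output. Stage failures are recorded in the manifest
#' rather than aborting the run.
#'
#' @param config configuration list, or path to a JSON file.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$master_seed)) 1L else as.integer(config$master_seed)
  manifest <- list(config = config, master_seed = seed,
                   package_version = as.character(utils::packageVersion("ddehm")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   outputs = character(0), errors = list())
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "train", "evaluate")
  study <- NULL
  get_study <- function() {
    if (!is.null(study)) return(study)
    sim_dir <- file.path(config$out_dir, "data")
    if (dir.exists(file.path(sim_dir, "train")))
      return(lapply(stats::setNames(nm = c("train", "valid", "test")),
                    function(s) read_dataset(file.path(sim_dir, s))))
    stop("no simulated data found; run the simulate stage first")
  }
  for (st in stages) {
    res <- tryCatch({
      if (st == "simulate") {
        case <- if (is.null(config$case)) "tfa" else config$case
        study <- make_case_study(case, config = config$sim %||% list(),
                                  master_seed = seed)
        sim_dir <- file.path(config$out_dir, "data")
        for (s in c("train", "valid", "test"))
          write_dataset(study[[s]], file.path(sim_dir, s), overwrite = TRUE)
        manifest$outputs <- c(manifest$outputs, sim_dir)
      } else if (st == "train") {
        study <- get_study()
        mc <- config$model %||% list()
        spec <- build_spec_from_config(mc)
        tc <- config$train %||% list()
        fit <- ddehm(spec, list(train = study$train, valid = study$valid),
                     restarts = tc$restarts %||% 3,
                     seed = derive_seed(seed, "train"),
                     control = do.call(ddehm_control,
                                       tc[setdiff(names(tc), "restarts")]))
        fp <- file.path(config$out_dir, "fit.json")
        write_fit(fit, fp)
        manifest$outputs <- c(manifest$outputs, fp)
      } else if (st == "gridsearch") {
        study <- get_study()
        gc <- config$grid %||% list()
        scan <- ddehm_grid(tfa_builder(),
                           nodes = gc$nodes %||% c(4, 5, 6),
                           delay_sets = as.list(gc$delays %||% c(0, 120)),
                           train = study$train, valid = study$valid,
                           test = study$test,
                           restarts = gc$restarts %||% 3,
                           seed = derive_seed(seed, "grid"),
                           control = do.call(ddehm_control,
                                             (gc$control %||% list())))
        tp <- file.path(config$out_dir, "selection_table.csv")
        utils::write.csv(scan$table, tp, row.names = FALSE)
        manifest$outputs <- c(manifest$outputs, tp)
      } else if (st == "evaluate") {
        study <- get_study()
        fp <- file.path(config$out_dir, "fit.json")
        stored <- read_fit(fp)
        spec <- build_spec_from_config(config$model %||% list())
        ev <- lapply(study[c("train", "valid", "test")], function(ds)
          c(E = objective_e(spec, stored$params, ds, stored$h),
            MSE = model_mse(spec, stored$params, ds, stored$h),
            BIC = model_bic(spec, stored$params, ds, stored$h)))
        ep <- file.path(config$out_dir, "evaluation.json")
        writeLines(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA), ep)
        manifest$outputs <- c(manifest$outputs, ep)
      } else stop("unknown stage: ", st)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) manifest$errors[[st]] <- res
  }
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$file_hashes <- as.list(tools::md5sum(files))
  mp <- file.path(config$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), mp)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_spec_from_config <- function(mc) {
  case <- mc$case %||% "tfa"
  if (case == "tfa") {
    tfa_spec(mc$structure %||% "1C", hidden = mc$hidden %||% 5,
             lags = mc$delay %||% 120)
  } else {
    pichia_spec(hidden = mc$hidden %||% 5,
                lags = if (is.null(mc$n_lags)) list(tau = 2.5, n = 4)
                else list(tau = mc$tau %||% 2.5, n = mc$n_lags))
  }
}
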