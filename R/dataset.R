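#' Time-series dataset of measured concentrations
#'
#' One or more experimental runs, each with a time grid, a measured
#' state matrix, per-variable standard deviations, optional exogenous
#' input records (e.g. feed rate), initial conditions and a split role.
#'
#' @param runs list of runs created by [ddehm_run()].
#' @param state_names character vector of state variable names.
#' @param exog_names character vector of exogenous column names (may be
#'   empty).
#' @return object of class `ddehm_dataset`.
#' @export
ddehm_dataset <- function(runs, state_names, exog_names = character()) {
  stopifnot(length(runs) >= 1)
  for (r in runs) {
    if (!identical(colnames(r$conc), state_names))
      stop("run state columns do not match dataset state names")
    if (length(exog_names) && !all(exog_names %in% colnames(r$exog)))
      stop("run exogenous columns do not match dataset exogenous names")
  }
  structure(list(runs = runs, state_names = state_names,
                 exog_names = exog_names),
            class = "ddehm_dataset")
}

#' Single run of a time-series dataset
#'
#' Validates the dataset invariants: strictly increasing times, positive
#' per-variable standard deviations, finite measurements.
#'
#' @param time numeric time grid.
#' @param conc measured state matrix (rows = time points), named columns.
#' @param sigma named per-variable standard deviations (> 0).
#' @param exog optional matrix of exogenous records (rows = time points).
#' @param x0 initial state (defaults to the first measured row).
#' @param role split role: `"train"`, `"valid"` or `"test"`.
#' @param clean optional noise-free state matrix (simulation studies).
#' @param config optional generating configuration (for reproducibility).
#' @return a run object (plain list) for [ddehm_dataset()].
#' @export
ddehm_run <- function(time, conc, sigma, exog = NULL, x0 = NULL,
                      role = c("train", "valid", "test"),
                      clean = NULL, config = NULL) {
  role <- match.arg(role)
  conc <- as.matrix(conc)
  if (is.null(colnames(conc))) stop("state matrix must have named columns")
  if (length(time) != nrow(conc)) stop("time/measurement length mismatch")
  if (any(diff(time) <= 0)) stop("run times must be strictly increasing")
  if (any(!is.finite(conc))) stop("non-finite measurements")
  sigma <- sigma[colnames(conc)]
  if (any(is.na(sigma)) || any(sigma <= 0))
    stop("per-variable standard deviations must be positive for every state")
  if (!is.null(exog)) {
    exog <- as.matrix(exog)
    if (nrow(exog) != length(time)) stop("exogenous record length mismatch")
  }
  if (is.null(x0)) x0 <- conc[1, ]
  list(time = time, conc = conc, sigma = sigma, exog = exog,
       x0 = x0, t0 = time[1], role = role, clean = clean, config = config)
}

#' @export
print.ddehm_dataset <- function(x, ...) {
  P <- sum(vapply(x$runs, function(r) length(r$time), 0))
  roles <- table(vapply(x$runs, function(r) r$role, ""))
  cat(sprintf("Dataset: %d run(s), %d samples, states: %s\n",
              length(x$runs), P, paste(x$state_names, collapse = ", ")))
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Total sample count and state count (the P and n of the objective).
dataset_dims <- function(dataset) {
  c(P = sum(vapply(dataset$runs, function(r) length(r$time), 0)),
    n = length(dataset$state_names))
}

#' Subset a dataset by split role
#' @param dataset a [ddehm_dataset()].
#' @param role one of `"train"`, `"valid"`, `"test"`.
#' @return a [ddehm_dataset()] with the matching runs.
#' @export
dataset_role <- function(dataset, role) {
  keep <- vapply(dataset$runs, function(r) identical(r$role, role), TRUE)
  if (!any(keep)) stop("no runs with role '", role, "'")
  ddehm_dataset(dataset$runs[keep], dataset$state_names, dataset$exog_names)
}

#' Split a pooled dataset into training and validation parts
#'
#' Assigns whole runs greedily so the training share of data points is
#' as close as possible to the requested fraction (the conventional
#' choice is about two thirds for training); runs are never split
#' internally because the delayed dynamics need contiguous records.
#'
#' @param dataset a [ddehm_dataset()].
#' @param train_frac target share of points for training (default 2/3).
#' @return list with elements `train` and `valid` ([ddehm_dataset()]s).
#' @export
split_dataset <- function(dataset, train_frac = 2 / 3) {
  np <- vapply(dataset$runs, function(r) length(r$time), 0)
  total <- sum(np)
  ord <- order(np, decreasing = TRUE)
  tr <- logical(length(np))
  acc <- 0
  for (i in ord) {
    if (acc < train_frac * total) { tr[i] <- TRUE; acc <- acc + np[i] }
  }
  if (all(tr)) tr[ord[length(ord)]] <- FALSE
  set_role <- function(r, role) { r$role <- role; r }
  list(train = ddehm_dataset(lapply(dataset$runs[tr], set_role, "train"),
                             dataset$state_names, dataset$exog_names),
       valid = ddehm_dataset(lapply(dataset$runs[!tr], set_role, "valid"),
                             dataset$state_names, dataset$exog_names))
}

# ---- on-disk format: tidy CSV + JSON sidecar -------------------------------

#' Write a dataset to disk
#'
#' One CSV per run (columns: `time`, state columns, exogenous columns)
#' plus a JSON sidecar carrying the per-variable standard deviations,
#' initial conditions, split role and generating configuration. Floats
#' are serialized with 17 significant digits so the round trip is exact.
#'
#' @param dataset a [ddehm_dataset()].
#' @param path directory to create/populate.
#' @param overwrite overwrite existing files.
#' @return invisibly, the files written.
#' @export
write_dataset <- function(dataset, path, overwrite = FALSE) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- character(0)
  for (k in seq_along(dataset$runs)) {
    r <- dataset$runs[[k]]
    base <- sprintf("run%02d", k)
    csv <- file.path(path, paste0(base, ".csv"))
    js <- file.path(path, paste0(base, ".json"))
    if (!overwrite && (file.exists(csv) || file.exists(js)))
      stop("refusing to overwrite ", csv, " (use overwrite = TRUE)")
    tab <- cbind(time = r$time, r$conc, r$exog)
    utils::write.csv(format(as.data.frame(tab), digits = 17, trim = TRUE),
                     csv, row.names = FALSE, quote = FALSE)
    meta <- list(states = dataset$state_names,
                 exog = dataset$exog_names,
                 sigma = as.list(r$sigma),
                 x0 = as.list(r$x0),
                 role = r$role,
                 config = r$config)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE), js)
    files <- c(files, csv, js)
  }
  invisible(files)
}

#' Read a dataset from disk
#'
#' Reads every `runNN.csv` / `runNN.json` pair written by
#' [write_dataset()], validating the dataset invariants (increasing
#' times, positive standard deviations, known columns).
#'
#' @param path dataset directory.
#' @return a [ddehm_dataset()].
#' @export
read_dataset <- function(path) {
  csvs <- sort(list.files(path, pattern = "^run[0-9]+\\.csv$", full.names = TRUE))
  if (!length(csvs)) stop("no run CSV files found in ", path)
  runs <- list()
  state_names <- NULL; exog_names <- NULL
  for (csv in csvs) {
    js <- sub("\\.csv$", ".json", csv)
    if (!file.exists(js)) stop("missing sidecar JSON for ", csv)
    meta <- jsonlite::fromJSON(js, simplifyVector = TRUE)
    tab <- utils::read.csv(csv, check.names = FALSE)
    if (!("time" %in% names(tab))) stop("missing 'time' column in ", csv)
    st <- as.character(meta$states)
    ex <- as.character(meta$exog)
    unknown <- setdiff(names(tab), c("time", st, ex))
    if (length(unknown)) stop("unknown columns in ", csv, ": ",
                              paste(unknown, collapse = ", "))
    if (is.null(state_names)) { state_names <- st; exog_names <- ex }
    sig <- unlist(meta$sigma)
    runs[[length(runs) + 1L]] <- ddehm_run(
      time = tab$time,
      conc = as.matrix(tab[, st, drop = FALSE]),
      sigma = sig,
      exog = if (length(ex)) as.matrix(tab[, ex, drop = FALSE]) else NULL,
      x0 = unlist(meta$x0),
      role = meta$role,
      config = meta$config)
  }
  ddehm_dataset(runs, state_names, exog_names)
}
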