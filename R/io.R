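#' Write / read a trial log
#'
#' Trial logs are plain comma-separated text with a header row, one trial
#' per row, carrying the design columns (block, sequence_id, trial_idx,
#' direction, the two options, reward ratio, interval, manipulation point)
#' plus any simulated columns (choice, rt, end_x).
#'
#' @param x A trial / choice-record data frame.
#' @param path File path.
#' @return `read_trial_log` returns a data frame.
#' @export
write_trial_log <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise a participant profile to a key-value text file
#'
#' @param profile A `participant_profile`.
#' @param path File path (YAML).
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(list(
    indifference_points = as.list(profile$indifference_points),
    discount_rate = profile$discount_rate,
    flagged = profile$flagged,
    diagnostics = if (!is.null(profile$diagnostics)) {
      lapply(as.list(profile$diagnostics), as.vector)
    }), path, precision = 17)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  raw <- yaml::read_yaml(path)
  ip <- unlist(raw$indifference_points)
  ip[ip == "NA"] <- NA
  participant_profile(vapply(ip, as.numeric, numeric(1)),
                      discount_rate = raw$discount_rate,
                      flagged = isTRUE(raw$flagged),
                      diagnostics = if (!is.null(raw$diagnostics)) {
                        as.data.frame(raw$diagnostics)
                      })
}

#' Read a run configuration file
#'
#' A YAML file with optional sections `attractor` (fields of
#' [attractor_params()]), `pcs` (fields of [pcs_params()]) and `cohort`
#' (fields of [simulate_cohort()] other than the chooser). Unset fields keep
#' their defaults.
#'
#' @param path Path to the YAML config.
#' @return A list with `attractor`, `pcs` and `cohort` elements.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  att <- do.call(attractor_params, raw$attractor %||% list())
  pcs_raw <- raw$pcs %||% list()
  if (!is.null(pcs_raw$importance)) {
    pcs_raw$importance <- unlist(pcs_raw$importance)
  }
  list(attractor = att, pcs = do.call(pcs_params, pcs_raw),
       cohort = raw$cohort %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort dataset directory
#'
#' A dataset directory holds one trial log per participant
#' (`participant_<id>.csv`) and a `manifest.yaml` carrying the ground-truth
#' parameters, the chooser specification, the master seed and the number of
#' replaced participants.
#'
#' @param dataset A `cohort_dataset` from [simulate_cohort()].
#' @param dir Directory path (created if missing).
#' @return `read_cohort` returns a list with `records` and `truth`.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in unique(dataset$records$participant)) {
    write_trial_log(dataset$records[dataset$records$participant == p, ],
                    file.path(dir, sprintf("participant_%03d.csv", p)))
  }
  chooser <- dataset$chooser
  yaml::write_yaml(list(
    n_participants = nrow(dataset$truth),
    master_seed = dataset$master_seed,
    n_replaced = dataset$n_replaced,
    chooser_kind = chooser$kind,
    truth = lapply(as.list(dataset$truth), as.vector)),
    file.path(dir, "manifest.yaml"), precision = 17)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^participant_.*\\.csv$",
                           full.names = TRUE))
  records <- do.call(rbind, lapply(files, read_trial_log))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  list(records = records, truth = as.data.frame(manifest$truth),
       manifest = manifest)
}
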