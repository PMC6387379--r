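#' Write and read detector event tables
#'
#' Events are exchanged as CSV with columns `time_s`, `kind`, `statistic`
#' (times in seconds from file start, referencing the start of the
#' triggering window). An empty event list produces a header-only file.
#'
#' @param events Event data frame as returned by the detectors.
#' @param path CSV path.
#' @return `path` invisibly (write); the event data frame (read).
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events),
            all(c("time_s", "kind", "statistic") %in% names(events)))
  utils::write.csv(events[c("time_s", "kind", "statistic")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "kind", "statistic") %in% names(ev))) {
    stop("event file must have columns time_s, kind, statistic",
         call. = FALSE)
  }
  ev
}

#' Read interval annotations for supervised training
#'
#' Annotation CSV format: one row per labelled interval with columns
#' `file`, `start_s`, `end_s`, `state` (`S`, `N`, `I`, `D` or `T`).
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_labels <- function(path) {
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("file", "start_s", "end_s", "state")
  if (!all(required %in% names(lab))) {
    stop("label file must have columns file, start_s, end_s, state",
         call. = FALSE)
  }
  if (any(lab$end_s < lab$start_s)) {
    stop("invalid labels: end_s precedes start_s", call. = FALSE)
  }
  bad <- setdiff(unique(lab$state), GUNSHOT_STATES)
  if (length(bad)) {
    stop(sprintf("invalid state label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  lab
}

#' Serialize a detector configuration to YAML
#'
#' One YAML document per detector embedding every parameter, so a
#' configuration can be stored beside the recordings it was used on.
#'
#' @param config A detector configuration (`bat_config()`, `cicada_config()`
#'   or `gunshot_config()`).
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "detector_config"))
  detector <- sub("_detector_config$", "", class(config)[1])
  body <- unclass(config)
  if (detector == "gunshot") body$model <- NULL # model travels as JSON
  yaml::write_yaml(c(list(detector = detector), body), path)
  invisible(path)
}

#' @rdname write_config
#' @param model For gunshot configurations, the [gunshot_hmm()] to attach
#'   (read separately with [read_gunshot_model()]).
#' @export
read_config <- function(path, model = NULL) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$detector)) {
    stop("configuration file lacks a `detector` field", call. = FALSE)
  }
  detector <- doc$detector
  doc$detector <- NULL
  switch(detector,
    bat = do.call(bat_config, doc),
    cicada = do.call(cicada_config, doc),
    gunshot = {
      doc$merge_window_s <- doc$merge_window_s %||% 2.048
      if (!is.null(model)) doc$model <- model
      do.call(gunshot_config, doc)
    },
    stop(sprintf("unknown detector kind '%s'", detector), call. = FALSE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Serialize a gunshot HMM to JSON
#'
#' The JSON schema holds the state names, the transition matrix (row
#' per source state), per-state/per-band log-normal `mu` and `sigma`, the
#' emission cap factor and the initial distribution.
#'
#' @param model A [gunshot_hmm()].
#' @param path JSON path.
#' @return `path` invisibly (write); a [gunshot_hmm()] (read).
#' @export
write_gunshot_model <- function(model, path) {
  stopifnot(inherits(model, "gunshot_hmm"))
  obj <- list(
    states = model$states,
    transition = unname(apply(model$transition, 1, as.numeric,
                              simplify = FALSE)),
    mu = unname(apply(model$mu, 1, as.numeric, simplify = FALSE)),
    sigma = unname(apply(model$sigma, 1, as.numeric, simplify = FALSE)),
    cap_factor = model$cap_factor,
    initial = as.numeric(model$initial)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gunshot_model
#' @export
read_gunshot_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(obj$states), GUNSHOT_STATES)) {
    stop("model file does not use the S, N, I, D, T state set", call. = FALSE)
  }
  as_matrix <- function(x, ncol) {
    if (is.matrix(x)) x else matrix(unlist(x), ncol = ncol, byrow = TRUE)
  }
  gunshot_hmm(
    as_matrix(obj$transition, 5),
    as_matrix(obj$mu, 3),
    as_matrix(obj$sigma, 3),
    cap_factor = obj$cap_factor,
    initial = obj$initial
  )
}
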