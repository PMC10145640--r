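#' Read and write tick and host tables
#'
#' Plain-CSV serialisation of the per-tick drop-off records and the per-host
#' metadata. `write_ticks()`/`write_hosts()` emit RFC-4180 CSV with a
#' documented header; the readers validate the schema and report offending
#' rows by file line number. Latent columns (`latent_whole_time`,
#' `latent_backward_time`, `latent_forward_time`) are written when present
#' and are optional on read.
#'
#' Tick schema: `host_id, capture_week, season, species, stage,
#' observed_day, status` (+ optional latent columns). Host schema:
#' `host_id, capture_week, season, sex, age_class, body_weight_kg`.
#'
#' @param ticks,hosts Data frames in the schemas above.
#' @param path File path.
#' @return The readers return validated data frames; writers return the path
#'   invisibly.
#' @name tick_io
NULL

#' @rdname tick_io
#' @export
write_ticks <- function(ticks, path) {
  keep <- intersect(ticks_columns(), names(ticks))
  write.csv(ticks[, keep, drop = FALSE], path, row.names = FALSE,
            quote = FALSE, eol = "\r\n")
  invisible(path)
}

#' @rdname tick_io
#' @export
read_ticks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("host_id", "capture_week", "season", "species", "stage",
                "observed_day", "status")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("tick file %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  fail_rows <- function(bad, what) {
    if (any(bad))
      stop(sprintf("invalid tick records in %s (%s) at line(s): %s", path,
                   what, paste(head(which(bad) + 1L, 5L), collapse = ", ")),
           call. = FALSE)
  }
  fail_rows(!df$season %in% tick_seasons(), "unknown season")
  fail_rows(!df$stage %in% tick_stages(), "unknown stage")
  fail_rows(!df$species %in% tick_species(), "unknown species")
  fail_rows(!df$status %in% tick_statuses(), "unknown status")
  fail_rows(!is.finite(df$observed_day) | df$observed_day <= 0,
            "observed_day must be positive")
  fail_rows(abs(df$observed_day %% 1 - 0.5) > 1e-9,
            "observed_day must be a half-integer day-bin midpoint")
  df
}

#' @rdname tick_io
#' @export
write_hosts <- function(hosts, path) {
  cols <- c("host_id", "capture_week", "season", "sex", "age_class",
            "body_weight_kg")
  write.csv(hosts[, intersect(cols, names(hosts)), drop = FALSE], path,
            row.names = FALSE, quote = FALSE, eol = "\r\n")
  invisible(path)
}

#' @rdname tick_io
#' @export
read_hosts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("host_id", "capture_week", "season")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("host file %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$host_id))
    stop(sprintf("duplicated host_id in %s", path), call. = FALSE)
  bad <- !df$season %in% tick_seasons()
  if (any(bad))
    stop(sprintf("unknown season in %s at line(s): %s", path,
                 paste(head(which(bad) + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  df
}

#' Read a simulator configuration from YAML or JSON
#'
#' Accepts the [sim_config()] fields; matrices are given as named lists of
#' named lists (`abundance_mean: {larva: {spring: 16.89, ...}, ...}`). A
#' `seed` entry is mandatory.
#'
#' @param path YAML (or JSON, a YAML subset) configuration file.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config must contain a 'seed'", call. = FALSE)
  as_matrix <- function(x) {
    if (is.null(x)) return(NULL)
    m <- sapply(tick_seasons(), function(se)
      sapply(tick_stages(), function(st) as.numeric(x[[st]][[se]])))
    rownames(m) <- tick_stages()
    m
  }
  args <- list(seed = raw$seed)
  if (!is.null(raw$n_hosts)) args$n_hosts <- raw$n_hosts
  if (!is.null(raw$capture_schedule))
    args$capture_schedule <- as.data.frame(raw$capture_schedule)
  if (!is.null(raw$abundance_mean))
    args$abundance_mean <- as_matrix(raw$abundance_mean)
  if (!is.null(raw$shape)) args$shape <- raw$shape
  if (!is.null(raw$scale)) args$scale <- as_matrix(raw$scale)
  for (f in c("frailty_sd", "duration_frailty_sd", "day1_suppression_prob",
              "suppress_stages", "hexagonus_fraction"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(sim_config, args)
}
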