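#' Parasitological summary of an infestation dataset
#'
#' Standard descriptive statistics of a drop-off dataset: mean intensity
#' (dropped ticks per host; by default all species are counted, mirroring
#' field practice, with a *ricinus*-only option), per-stage prevalence
#' (fraction of hosts yielding at least one tick of that stage), stage
#' composition of the *I. ricinus* ticks, species composition, and
#' per-stage drop-off status proportions (dead / imperfect blood meal).
#'
#' @param ticks Tick records ([read_ticks()] schema).
#' @param hosts Host table covering every `host_id` in `ticks`.
#' @param intensity_species `"all"` or `"ricinus"`.
#' @return List of class `infestation_summary`.
#' @export
cohort_summary <- function(ticks, hosts, intensity_species = c("all", "ricinus")) {
  intensity_species <- match.arg(intensity_species)
  if (is.null(hosts) || nrow(hosts) == 0L)
    stop("host table is empty", call. = FALSE)
  extra <- setdiff(unique(ticks$host_id), hosts$host_id)
  if (length(extra))
    stop("tick records refer to unknown hosts: ",
         paste(head(extra, 3), collapse = ", "), call. = FALSE)
  n_hosts <- nrow(hosts)
  ric <- ticks[ticks$species == "ricinus", , drop = FALSE]
  counted <- if (intensity_species == "all") ticks else ric

  prevalence <- vapply(tick_stages(), function(s)
    length(unique(ric$host_id[ric$stage == s])) / n_hosts, 0)
  stage_tot <- vapply(tick_stages(), function(s) sum(ric$stage == s), 0)
  status <- lapply(tick_stages(), function(s) {
    st <- ric$status[ric$stage == s]
    if (!length(st)) return(c(dead = NA_real_, imperfect = NA_real_))
    c(dead = mean(st == "dead"), imperfect = mean(st == "imperfect"))
  })
  names(status) <- tick_stages()

  structure(list(
    n_hosts = n_hosts,
    n_ticks = nrow(ticks),
    mean_intensity = nrow(counted) / n_hosts,
    intensity_species = intensity_species,
    prevalence = prevalence,
    stage_totals = stage_tot,
    stage_composition = if (sum(stage_tot) > 0) stage_tot / sum(stage_tot)
                        else stage_tot,
    species_composition = c(
      ricinus = nrow(ric) / max(nrow(ticks), 1),
      hexagonus = sum(ticks$species == "hexagonus") / max(nrow(ticks), 1)),
    status_props = status
  ), class = "infestation_summary")
}

#' Summary statistics from printed stage totals
#'
#' The totals-level counterpart of [cohort_summary()], for use with the
#' bundled study tables where per-host records are not available: takes
#' *I. ricinus* totals per stage, the *I. hexagonus* count, the number of
#' hosts, and optional per-stage status counts.
#'
#' @param stage_totals Named vector of *I. ricinus* counts per stage
#'   (names from `larva, nymph, female, male`).
#' @param n_hosts Number of examined hosts.
#' @param hexagonus *I. hexagonus* count (counted into the intensity, as in
#'   field totals).
#' @param status Optional data frame `stage, total, dead, imperfect` giving
#'   the denominators actually scored for status.
#' @return List of class `infestation_summary` (prevalence unavailable:
#'   `NA`).
#' @examples
#' fx <- study_fixtures()
#' s <- totals_summary(fx$stage_totals, n_hosts = 57, hexagonus = 31,
#'                     status = fx$status)
#' s$mean_intensity
#' @export
totals_summary <- function(stage_totals, n_hosts, hexagonus = 0,
                           status = NULL) {
  stopifnot(all(names(stage_totals) %in% tick_stages()), n_hosts > 0)
  tot_ric <- sum(stage_totals)
  total <- tot_ric + hexagonus
  status_props <- NULL
  if (!is.null(status)) {
    status_props <- lapply(seq_len(nrow(status)), function(i)
      c(dead = status$dead[i] / status$total[i],
        imperfect = status$imperfect[i] / status$total[i]))
    names(status_props) <- status$stage
  }
  structure(list(
    n_hosts = n_hosts,
    n_ticks = total,
    mean_intensity = total / n_hosts,
    intensity_species = "all",
    prevalence = setNames(rep(NA_real_, 4), tick_stages()),
    stage_totals = stage_totals[tick_stages()],
    stage_composition = stage_totals[tick_stages()] / tot_ric,
    species_composition = c(ricinus = tot_ric / total,
                            hexagonus = hexagonus / total),
    status_props = status_props
  ), class = "infestation_summary")
}

#' @export
print.infestation_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Infestation summary: %d ticks on %d hosts\n",
              round(x$n_ticks), x$n_hosts))
  cat(sprintf("Mean intensity (%s species): %.2f ticks/host\n",
              x$intensity_species, x$mean_intensity))
  cat(sprintf("Species: %.2f%% ricinus, %.2f%% hexagonus\n",
              100 * x$species_composition["ricinus"],
              100 * x$species_composition["hexagonus"]))
  cat("Stage composition (I. ricinus, %):\n")
  print(round(100 * x$stage_composition, 1))
  if (!all(is.na(x$prevalence))) {
    cat("Prevalence per stage:\n"); print(round(x$prevalence, digits))
  }
  if (!is.null(x$status_props)) {
    cat("Status proportions (dead / imperfect):\n")
    for (s in names(x$status_props))
      cat(sprintf("  %-7s %6.2f%% / %.2f%%\n", s,
                  100 * x$status_props[[s]]["dead"],
                  100 * x$status_props[[s]]["imperfect"]))
  }
  invisible(x)
}

#' Weekly drop-off series
#'
#' Counts ticks per capture week of their host, densely over the study
#' window (weeks without captures or drop-offs get zero).
#'
#' @param ticks Tick records with `capture_week`.
#' @param stage Optional stage filter.
#' @param weeks Integer vector of weeks defining the window; default
#'   `1:max(capture_week)` (or `integer(0)` for empty input).
#' @return Named integer vector of counts per week.
#' @export
weekly_series <- function(ticks, stage = NULL, weeks = NULL) {
  tk <- if (is.null(stage)) ticks
        else ticks[ticks$stage %in% stage, , drop = FALSE]
  if (is.null(weeks))
    weeks <- if (nrow(ticks)) seq_len(max(ticks$capture_week)) else integer(0)
  out <- setNames(integer(length(weeks)), weeks)
  if (nrow(tk)) {
    tab <- table(factor(tk$capture_week, levels = weeks))
    out[] <- as.integer(tab)
  }
  out
}

#' Count activity peaks in a weekly series
#'
#' A peak is a strict local maximum (greater than both neighbours; a
#' plateau of equal values counts once, at its left edge) whose topographic
#' prominence reaches `min_prominence`. Prominence is the peak height minus
#' the higher of the two lowest points separating the peak from higher
#' ground on each side (series edges count as ground). Endpoints are never
#' peaks.
#'
#' @param series Numeric vector, length >= 3.
#' @param min_prominence Non-negative prominence threshold (counts).
#' @return Integer number of peaks.
#' @examples
#' count_peaks(c(0, 5, 0, 5, 0), 1)        # 2
#' count_peaks(c(0, 3, 3, 3, 0, 7, 0), 1)  # 2: plateau counted once
#' @export
count_peaks <- function(series, min_prominence = 1) {
  if (min_prominence < 0) stop("'min_prominence' must be >= 0", call. = FALSE)
  n <- length(series)
  if (n < 3L) stop("series must have length >= 3", call. = FALSE)
  peaks <- 0L
  i <- 2L
  while (i < n) {
    if (series[i] > series[i - 1L]) {
      j <- i                       # absorb any plateau to the right
      while (j < n && series[j + 1L] == series[i]) j <- j + 1L
      if (j < n && series[j + 1L] < series[i]) {
        h <- series[i]
        left <- min(series[seq_len(i - 1L)])
        l <- i - 1L
        while (l >= 1L && series[l] <= h) l <- l - 1L
        if (l >= 1L) left <- min(series[(l + 1L):(i - 1L)])
        right <- min(series[(j + 1L):n])
        r <- j + 1L
        while (r <= n && series[r] <= h) r <- r + 1L
        if (r <= n) right <- min(series[(j + 1L):(r - 1L)])
        if (h - max(left, right) >= min_prominence) peaks <- peaks + 1L
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}
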