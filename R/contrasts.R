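#' Log cell-mean estimates exposed for contrast building
#'
#' Internal generic: a fit must expose a named vector of log cell means
#' (named `"stage:season"`, or `"stage"` for stage-only fits) and their
#' covariance. For the abundance model these are log mean ticks per host;
#' for the attachment-time model they are log Weibull scales, whose
#' differences equal differences of log mean whole (and observed)
#' attachment times because the shape is common.
#'
#' @param object A fitted model.
#' @return List with `log_means` and `vcov`.
#' @keywords internal
cell_estimates <- function(object) UseMethod("cell_estimates")

#' @export
cell_estimates.abundance_fit <- function(object) {
  keep <- !(names(object$log_means) %in% object$boundary_cells)
  list(log_means = object$log_means[keep],
       vcov = object$vcov[keep, keep, drop = FALSE])
}

#' @export
cell_estimates.fraft <- function(object) {
  vars <- all.vars(delete.response(object$terms))
  cells <- unique(object$model[, vars, drop = FALSE])
  tt <- delete.response(object$terms)
  X <- model.matrix(tt, model.frame(tt, cells, xlev = object$xlevels))
  lm <- drop(X %*% object$coefficients)
  p <- length(object$coefficients)
  V <- X %*% object$vcov[seq_len(p), seq_len(p)] %*% t(X)
  nm <- do.call(paste, c(lapply(cells, as.character), sep = ":"))
  list(log_means = setNames(lm, nm),
       vcov = matrix(V, nrow(X), dimnames = list(nm, nm)))
}

#' Post hoc ratio contrasts between modelled cell means
#'
#' Pairwise comparisons of modelled means — between tick stages within each
#' season (`"stage_within_season"`) or between seasons within each stage
#' (`"season_within_stage"`) — reported as ratios with simultaneous
#' confidence intervals and multiplicity-adjusted p-values. Works on any
#' fit exposing log cell means and their covariance ([abundance_fit()],
#' [fraft()] with stage/season covariates).
#'
#' The default adjustment is the single-step max-|z| method: the joint
#' normal distribution of the standardised contrasts is sampled
#' (`nsim` draws, fixed `seed` so results are reproducible) and each
#' adjusted p-value is the probability that the largest absolute
#' standardised deviate exceeds the observed one; the same distribution
#' yields the critical value for the simultaneous intervals. `"holm"` gives
#' the deterministic step-down fallback (with per-comparison intervals),
#' `"none"` unadjusted results.
#'
#' @param object A fitted model with a [cell_estimates()] method.
#' @param family Which family of pairwise comparisons.
#' @param adjust Multiplicity adjustment.
#' @param level Simultaneous confidence level.
#' @param nsim Monte-Carlo draws for the single-step adjustment.
#' @param seed Seed for those draws (caller's RNG stream is untouched).
#' @return Data frame of class `cell_contrasts`: `family`, `label`,
#'   `estimate` (ratio), `lower`, `upper`, `z`, `p_raw`, `p_adjusted`.
#' @examples
#' fit <- abundance_fit(cells = study_fixtures()$table2)
#' cell_contrasts(fit, "stage_within_season")
#' @export
cell_contrasts <- function(object,
                           family = c("stage_within_season",
                                      "season_within_stage"),
                           adjust = c("single-step", "holm", "none"),
                           level = 0.95, nsim = 1e5, seed = 20230329) {
  family <- match.arg(family)
  adjust <- match.arg(adjust)
  est <- cell_estimates(object)
  cells <- strsplit(names(est$log_means), ":", fixed = TRUE)
  has_season <- lengths(cells) >= 2L
  stage <- vapply(cells, `[`, "", 1L)
  season <- if (all(has_season)) vapply(cells, `[`, "", 2L)
            else rep("all", length(cells))
  if (family == "season_within_stage" && length(unique(season)) < 2L)
    stop("fit has no season dimension to compare within stages",
         call. = FALSE)

  C <- NULL; labels <- character(0)
  add <- function(i, j, lab) {
    row <- numeric(length(stage)); row[i] <- 1; row[j] <- -1
    C <<- rbind(C, row); labels <<- c(labels, lab)
  }
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  if (family == "stage_within_season") {
    pairs <- list(c("female", "male"), c("larva", "male"),
                  c("nymph", "male"), c("female", "larva"),
                  c("nymph", "larva"), c("female", "nymph"))
    for (se in unique(season)) for (pr in pairs) {
      i <- which(stage == pr[1] & season == se)
      j <- which(stage == pr[2] & season == se)
      if (length(i) == 1 && length(j) == 1)
        add(i, j, sprintf("%s %s/%s", cap(se), cap(pr[1]), cap(pr[2])))
    }
  } else {
    pairs <- list(c("summer", "spring"), c("autumn", "spring"),
                  c("autumn", "summer"))
    for (st in unique(stage)) for (pr in pairs) {
      i <- which(stage == st & season == pr[1])
      j <- which(stage == st & season == pr[2])
      if (length(i) == 1 && length(j) == 1)
        add(i, j, sprintf("%s %s/%s", cap(st), cap(pr[1]), cap(pr[2])))
    }
  }
  if (is.null(C) || nrow(C) < 1L)
    stop("contrast family has no comparable pairs", call. = FALSE)

  delta <- drop(C %*% est$log_means)
  CV <- C %*% est$vcov %*% t(C)
  se <- sqrt(pmax(diag(CV), 0))
  z <- ifelse(se > 0, delta / se, 0)
  p_raw <- 2 * pnorm(-abs(z))
  p_raw[se == 0] <- 1

  if (adjust == "single-step") {
    pos <- se > 0
    R <- cov2cor(CV[pos, pos, drop = FALSE] +
                   diag(1e-12, sum(pos)))
    L <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, nrow(R))))
    maxabs <- with_local_seed(seed, {
      Z <- matrix(rnorm(nsim * nrow(R)), nsim) %*% L
      apply(abs(Z), 1L, max)
    })
    p_adj <- rep(1, length(z))
    p_adj[pos] <- vapply(abs(z[pos]),
                         function(a) mean(maxabs >= a), 0)
    p_adj <- pmax(p_adj, p_raw)      # max-|z| dominates the marginal test
    crit <- unname(quantile(maxabs, level))
  } else if (adjust == "holm") {
    p_adj <- p.adjust(p_raw, "holm")
    crit <- qnorm(1 - (1 - level) / 2)
  } else {
    p_adj <- p_raw
    crit <- qnorm(1 - (1 - level) / 2)
  }

  out <- data.frame(family = family, label = labels,
                    estimate = exp(delta),
                    lower = exp(delta - crit * se),
                    upper = exp(delta + crit * se),
                    z = z, p_raw = p_raw, p_adjusted = pmin(p_adj, 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cell_contrasts", "data.frame")
  out
}

#' @export
print.cell_contrasts <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$estimate <- round(y$estimate, digits)
  y$lower <- round(y$lower, digits)
  y$upper <- round(y$upper, digits)
  y$z <- round(y$z, 2)
  y$p_raw <- signif(y$p_raw, 2)
  y$p_adjusted <- signif(y$p_adjusted, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
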