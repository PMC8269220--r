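#' A sparse cell-density growth curve
#'
#' @param times hours, strictly increasing.
#' @param densities cells/ml, strictly positive (zeros are rejected: the
#'   log2 transform that defines rates in doublings/h requires positive
#'   counts).
#' @param replicate_id label.
#' @return object of class `ecophys_curve`.
#' @export
growth_curve <- function(times, densities, replicate_id = "rep1") {
  stopifnot(length(times) == length(densities))
  if (length(times) < 2) stop("a growth curve needs at least 2 observations")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(densities <= 0)) stop("densities must be strictly positive")
  structure(list(replicate_id = replicate_id, times = as.numeric(times),
                 densities = as.numeric(densities)),
            class = "ecophys_curve")
}

#' Read long-format growth data
#'
#' TSV/CSV with columns `condition`, `replicate`, `time_h`, `cells_per_ml`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return nested list: condition -> replicate -> `ecophys_curve`.
#' @export
read_growth_data <- function(path, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c("condition", "replicate", "time_h", "cells_per_ml")
  if (!all(needed %in% names(tab))) {
    stop("growth data needs columns: ", paste(needed, collapse = ", "))
  }
  lapply(split(tab, tab$condition), function(cond) {
    lapply(split(cond, cond$replicate), function(rep) {
      rep <- rep[order(rep$time_h), ]
      growth_curve(rep$time_h, rep$cells_per_ml, rep$replicate[1])
    })
  })
}

## Plain least squares of y on x; returns everything the phase tables need.
## Much faster than lm() inside the exhaustive segmentation search.
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - my)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  df <- n - 2
  p <- if (df < 1) {
    NA_real_
  } else {
    sigma2 <- rss / df
    if (sigma2 < 1e-24) {            # numerically perfect fit
      if (abs(slope) > 1e-12) 0 else 1
    } else {
      se <- sqrt(sigma2 / sxx)
      2 * stats::pt(abs(slope) / se, df, lower.tail = FALSE)
    }
  }
  list(slope = slope, intercept = intercept, rss = rss, r2 = r2, p = p)
}

## All segmentations of n ordered points into 1..max_seg contiguous runs of
## at least min_points each, as lists of start indices.
.segmentations <- function(n, min_points, max_seg = 3) {
  out <- list(c(1L))
  if (max_seg >= 2 && n >= 2 * min_points) {
    for (b in seq(min_points + 1L, n - min_points + 1L)) {
      out[[length(out) + 1L]] <- c(1L, b)
    }
  }
  if (max_seg >= 3 && n >= 3 * min_points) {
    for (b1 in seq(min_points + 1L, n - 2 * min_points + 1L)) {
      for (b2 in seq(b1 + min_points, n - min_points + 1L)) {
        out[[length(out) + 1L]] <- c(1L, b1, b2)
      }
    }
  }
  out
}

#' Segment a sparse growth curve and fit per-phase log-linear rates
#'
#' The curve's log2 densities are split into at most three contiguous phases
#' by exhaustive search over breakpoints (each phase spanning at least
#' `min_points` observations). The number and position of breakpoints are
#' chosen by minimizing a Bayesian-information-criterion score on the pooled
#' residual sum of squares, with ties broken toward fewer phases and then
#' earlier breakpoints, so the procedure is fully deterministic. Within each
#' phase an ordinary least squares fit of log2(density) on time gives the
#' specific rate directly in doublings/h. Phases whose slope is statistically
#' indistinguishable from zero (t-test p >= 0.05) or whose fitted fold change
#' is below `min_fold_change` are called stationary and excluded from the
#' returned table.
#'
#' @param curve an `ecophys_curve`.
#' @param min_points minimum observations per phase (>= 3).
#' @param min_fold_change minimum fitted fold change for a phase to count as
#'   growth or death (default 2).
#' @return data frame with one row per growth/death phase: `replicate_id`,
#'   `kind` ("growth"/"death"), `start_index`, `end_index`, `rate`
#'   (doublings/h), `intercept` (log2 cells/ml), `r_squared`, `p_value`,
#'   `fold_change`. Curves shorter than `min_points` return an empty table
#'   with a warning.
#' @export
segment_and_fit <- function(curve, min_points = 3, min_fold_change = 2) {
  stopifnot(inherits(curve, "ecophys_curve"), min_points >= 3)
  empty <- data.frame(replicate_id = character(), kind = character(),
                      start_index = integer(), end_index = integer(),
                      rate = numeric(), intercept = numeric(),
                      r_squared = numeric(), p_value = numeric(),
                      fold_change = numeric(), stringsAsFactors = FALSE)
  n <- length(curve$times)
  if (n < min_points) {
    warning("curve '", curve$replicate_id, "' has fewer than ", min_points,
            " observations; no phases fitted")
    return(empty)
  }
  t <- curve$times
  y <- log2(curve$densities)

  segs <- .segmentations(n, min_points)
  score <- function(starts) {
    ends <- c(starts[-1] - 1L, n)
    fits <- Map(function(s, e) .ols(t[s:e], y[s:e]), starts, ends)
    rss <- sum(vapply(fits, `[[`, 0, "rss"))
    k <- 3 * length(starts) - 1          # slope+intercept per phase, breakpoints
    bic <- n * log(max(rss, n * 1e-20) / n) + k * log(n)
    list(bic = bic, fits = fits, starts = starts, ends = ends)
  }
  scored <- lapply(segs, score)
  bics <- vapply(scored, `[[`, 0, "bic")
  cand <- which(bics <= min(bics) + 1e-9)
  ## ties: fewer phases first, then lexicographically earlier breakpoints
  ord <- order(vapply(scored[cand], function(s) length(s$starts), 0L),
               vapply(scored[cand], function(s) paste(sprintf("%04d", s$starts),
                                                      collapse = ""), ""))
  best <- scored[[cand[ord[1]]]]

  rows <- lapply(seq_along(best$starts), function(i) {
    f <- best$fits[[i]]
    s <- best$starts[i]; e <- best$ends[i]
    span <- t[e] - t[s]
    fc <- 2^(abs(f$slope) * span)
    stationary <- is.na(f$p) || f$p >= 0.05 || fc < min_fold_change
    if (stationary) return(NULL)
    data.frame(replicate_id = curve$replicate_id,
               kind = if (f$slope > 0) "growth" else "death",
               start_index = s, end_index = e, rate = f$slope,
               intercept = f$intercept, r_squared = f$r2, p_value = f$p,
               fold_change = fc, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Maximum specific growth rate across fitted phases
#'
#' @param fits phase table from [segment_and_fit()] (possibly row-bound over
#'   curves).
#' @return largest positive rate in doublings/h, or `NA` with a warning of
#'   class `ecophys_no_growth` when no growth phase was detected — the
#'   "no growth detected" call, distinct from a rate of zero.
#' @export
max_growth_rate <- function(fits) {
  growth <- fits[fits$kind == "growth", , drop = FALSE]
  if (!nrow(growth)) {
    warning(warningCondition("no growth detected",
                             class = c("ecophys_no_growth", "warning")))
    return(NA_real_)
  }
  max(growth$rate)
}

#' Summarize replicate growth rates
#'
#' @param rates numeric vector of per-replicate rates (doublings/h).
#' @return list with `mean_rate`, `sd_rate` (sample sd, `NA` for a single
#'   replicate), `n_replicates` and `doubling_time` (h; `NA` unless the mean
#'   rate is positive).
#' @export
summarize_replicates <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (!length(rates)) stop("no rates to summarize")
  m <- mean(rates)
  list(mean_rate = m,
       sd_rate = if (length(rates) > 1) stats::sd(rates) else NA_real_,
       n_replicates = length(rates),
       doubling_time = if (m > 0) 1 / m else NA_real_)
}

#' Growth-yield ratio of treatment to control
#'
#' 100 x mean(treatment maximum densities) / mean(control maximum
#' densities); used to compare lithoautotrophic and heterotrophic yields.
#'
#' @param treatment_max_densities,control_max_densities cells/ml vectors of
#'   per-replicate maximum densities.
#' @return percentage.
#' @examples
#' yield_ratio(1.26e6, 1.85e6)  # about 68
#' @export
yield_ratio <- function(treatment_max_densities, control_max_densities) {
  if (!length(treatment_max_densities) || !length(control_max_densities)) {
    stop("both density lists must be nonempty")
  }
  ctl <- mean(control_max_densities)
  if (ctl == 0) stop("control mean density is zero")
  100 * mean(treatment_max_densities) / ctl
}
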