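#' @include AllClasses.R
NULL

#' Fit the exponential activity-distance relation
#'
#' Nonlinear least-squares fit of `activity = b * exp(-c * distance)`,
#' initialized from the log-linear closed form on positive activities (with a
#' direct nonlinear start when activities are non-positive).  The distances
#' are typically per-variant mean catalytic-cysteine to substrate-lysine
#' side-chain distances (nm) averaged over replicates; replicate
#' uncertainties may be supplied for reporting but the fit is unweighted.
#'
#' The reported correlation is the Pearson correlation between observed and
#' fitted activities.  A degenerate fit (e.g. constant activities, where the
#' correlation is undefined) reports correlation 0 with the `degenerate`
#' flag set.
#'
#' @param distances numeric distances (nm), all > 0, length >= 3.
#' @param activities numeric activities, same length.
#' @param uncertainties optional per-point distance uncertainties, carried
#'   into the report only.
#' @return an [ActivityFit-class].
#' @seealso [predictActivity()]
#' @export
fitExponentialActivity <- function(distances, activities,
                                   uncertainties = NULL) {
  x <- as.numeric(distances)
  y <- as.numeric(activities)
  if (length(x) != length(y)) {
    .err("invalid_argument", "distances and activities differ in length")
  }
  if (length(x) < 3L) .err("invalid_argument", "need at least 3 points")
  if (any(x <= 0)) .err("invalid_argument", "all distances must be > 0")
  if (stats::sd(y) == 0) {
    return(methods::new("ActivityFit", b = mean(y), c = 0, correlation = 0,
                        residuals = rep(0, length(y)), fitted = y,
                        distances = x, activities = y, degenerate = TRUE))
  }
  pos <- y > 0
  if (sum(pos) >= 2L) {
    ll <- stats::lm(log(y[pos]) ~ x[pos])
    b0 <- exp(unname(stats::coef(ll)[1L]))
    c0 <- -unname(stats::coef(ll)[2L])
  } else {
    b0 <- max(abs(y))
    c0 <- 1
  }
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b * exp(-c * x), data = dat,
                      start = list(b = b0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) .err("invalid_argument",
                             sprintf("exponential fit failed: %s",
                                     conditionMessage(e))))
  cf <- stats::coef(fit)
  fitted <- unname(cf["b"]) * exp(-unname(cf["c"]) * x)
  degen <- stats::sd(fitted) == 0
  corr <- if (degen) 0 else stats::cor(y, fitted)
  if (is.na(corr)) { corr <- 0; degen <- TRUE }
  methods::new("ActivityFit", b = unname(cf["b"]), c = unname(cf["c"]),
               correlation = corr, residuals = y - fitted, fitted = fitted,
               distances = x, activities = y, degenerate = degen)
}

#' Evaluate a fitted exponential activity model
#'
#' @param x distance(s) in nm.
#' @param fit an [ActivityFit-class].
#' @return predicted activity `b * exp(-c * x)`.
#' @export
predictActivity <- function(x, fit) {
  fit@b * exp(-fit@c * x)
}
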