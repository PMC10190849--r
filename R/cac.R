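# Critical aggregation concentration from Thioflavin T titrations:
# two-segment (broken-stick) least squares on log2 concentration with a
# slope-increase validity criterion, plus the synthetic titration
# generator used for calibration studies.

#' Construct a validated ThT titration curve
#'
#' @param concentration strictly increasing positive concentrations, uM
#'   (at least 5 doses)
#' @param fluorescence non-negative fluorescence readings, arbitrary units
#' @param molecule,replicate optional identifiers carried through
#' @return a data frame of class `titration_curve`
#' @export
titration_curve <- function(concentration, fluorescence, molecule = NA,
                            replicate = NA) {
  concentration <- as.numeric(concentration)
  fluorescence <- as.numeric(fluorescence)
  if (length(concentration) != length(fluorescence))
    stop("concentration and fluorescence lengths differ")
  if (length(concentration) < 5L)
    stop("a titration curve needs at least 5 doses")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(fluorescence < 0)) stop("fluorescence must be non-negative")
  structure(data.frame(concentration = concentration,
                       fluorescence = fluorescence,
                       molecule = molecule, replicate = replicate,
                       stringsAsFactors = FALSE),
            class = c("titration_curve", "data.frame"))
}

#' Generate a synthetic ThT titration curve
#'
#' Emulates a dose-dependent aggregation profile: fluorescence is a
#' continuous two-segment linear function of log2 concentration with a
#' breakpoint at the critical aggregation concentration, a shallow
#' pre-breakpoint slope (free dye background) and a steep post-breakpoint
#' slope (beta-sheet intercalation), under multiplicative Gaussian noise.
#' A breakpoint above the largest dose yields a background-only curve.
#'
#' @param cac planted breakpoint, uM
#' @param doses dose grid, uM; default eight two-fold dilutions
#'   3.125-400 uM
#' @param pre_slope,post_slope fluorescence change per concentration
#'   doubling below/above the breakpoint (arbitrary units; the
#'   aggregation signal requires `post_slope > pre_slope`)
#' @param baseline fluorescence at the lowest dose
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed integer seed for reproducibility (`NULL`: current RNG state)
#' @param molecule,replicate identifiers carried into the curve
#' @return a `titration_curve`; the planted breakpoint is stored in
#'   attribute `"planted_cac"`
#' @examples
#' tc <- generate_titration(25, noise_cv = 0.05, seed = 1)
#' fit_cac(tc)
#' @export
generate_titration <- function(cac, doses = 3.125 * 2^(0:7),
                               pre_slope = 5, post_slope = 300,
                               baseline = 100, noise_cv = 0, seed = NULL,
                               molecule = NA, replicate = NA) {
  stopifnot(cac > 0, length(doses) >= 5L, noise_cv >= 0)
  if (post_slope <= pre_slope)
    stop("aggregating curves require post_slope > pre_slope")
  l <- log2(doses)
  mu <- baseline + pre_slope * (l - l[1]) +
    (post_slope - pre_slope) * pmax(l - log2(cac), 0)
  y <- mu
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- mu * (1 + rnorm(length(mu), 0, noise_cv))
    y <- pmax(y, 0)
  }
  tc <- titration_curve(doses, y, molecule = molecule,
                        replicate = replicate)
  attr(tc, "planted_cac") <- cac
  tc
}

#' Fit the critical aggregation concentration by breakpoint regression
#'
#' Fits a continuous two-segment linear model of fluorescence against
#' log2 concentration, `y = a + b1 (l - c) + (b2 - b1) max(l - c, 0)`,
#' minimising the residual sum of squares over a deterministic grid of
#' candidate breakpoints: the interior dose points plus `grid_points`
#' equal subdivisions of each interior dose interval (so refining the
#' grid can only lower the RSS). A fit is a valid aggregation call only
#' if the post-breakpoint slope exceeds the pre-breakpoint slope and the
#' two-segment model improves significantly on a single line (F test at
#' `alpha`); otherwise the estimate is censored as ">= max tested dose",
#' mirroring how soluble designs are reported.
#'
#' @param curve a [titration_curve()] (or data frame with columns
#'   `concentration`, `fluorescence`)
#' @param grid_points subdivisions per interior dose interval
#' @param alpha significance level of the slope-increase F test
#' @param nboot optional number of bootstrap replicates (multiplicative
#'   residual resampling) for a percentile confidence interval
#' @return an object of class `cac_fit` with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot`. Components:
#'   `cac` (uM; `NA` when censored), `censored`, `max_dose`,
#'   `breakpoint_log2`, `coefficients` (`intercept`, `slope_pre`,
#'   `slope_post`), `rss`, `p_value`, `ci` (when bootstrapped)
#' @export
fit_cac <- function(curve, grid_points = 20L, alpha = 0.05, nboot = 0L) {
  if (!inherits(curve, "titration_curve"))
    curve <- titration_curve(curve$concentration, curve$fluorescence,
                             molecule = curve$molecule[1] %||% NA)
  l <- log2(curve$concentration)
  y <- curve$fluorescence
  n <- length(y)

  # candidate breakpoints: interior dose points + nested subdivisions
  lo <- l[2]; hi <- l[n - 1L]
  cand <- unique(sort(unlist(lapply(2:(n - 2L), function(k)
    l[k] + (l[k + 1L] - l[k]) * (0:grid_points) / grid_points))))
  cand <- cand[cand >= lo & cand <= hi]

  fit_at <- function(cc) {
    X <- cbind(1, l - cc, pmax(l - cc, 0))
    f <- lm.fit(X, y)
    list(rss = sum(f$residuals^2), coef = f$coefficients,
         fitted = f$fitted.values)
  }
  fits <- lapply(cand, fit_at)
  rss <- vapply(fits, `[[`, 0, "rss")
  dslope <- vapply(fits, function(f) f$coef[3], 0)

  valid <- which(dslope > 1e-12)
  line0 <- lm.fit(cbind(1, l), y)
  rss0 <- sum(line0$residuals^2)

  censored <- TRUE
  best <- NULL; cbest <- NA_real_; pval <- NA_real_
  if (length(valid)) {
    k <- valid[which.min(rss[valid])]
    best <- fits[[k]]; cbest <- cand[k]
    # snap breakpoints landing on a dose point to that dose exactly
    snap <- which(abs(l - cbest) < 1e-9)
    if (length(snap)) cbest <- l[snap[1]]
    # slope-increase significance: 2 extra parameters vs a single line
    if (best$rss < 1e-20 && rss0 > 1e-12) {
      pval <- 0
    } else if (best$rss > 0) {
      Fstat <- ((rss0 - best$rss) / 2) / (best$rss / (n - 4))
      pval <- pf(Fstat, 2, n - 4, lower.tail = FALSE)
    } else pval <- 1   # flat degenerate data
    censored <- !is.finite(pval) || pval > alpha
  }

  b1 <- if (is.null(best)) unname(line0$coefficients[2]) else unname(best$coef[2])
  b2 <- if (is.null(best)) b1 else unname(best$coef[2] + best$coef[3])

  cac_value <- if (censored) NA_real_ else {
    v <- 2^cbest
    hit <- which(abs(log2(curve$concentration) - cbest) < 1e-9)
    if (length(hit)) v <- curve$concentration[hit[1]]
    v
  }
  obj <- structure(list(
    cac = cac_value,
    censored = censored,
    max_dose = max(curve$concentration),
    breakpoint_log2 = if (censored) NA_real_ else cbest,
    coefficients = c(intercept = if (is.null(best))
                       unname(line0$coefficients[1]) else unname(best$coef[1]),
                     slope_pre = b1, slope_post = b2),
    rss = if (is.null(best)) rss0 else best$rss,
    p_value = pval,
    fitted_values = if (is.null(best)) line0$fitted.values else best$fitted,
    data = curve,
    grid = data.frame(breakpoint_log2 = cand, rss = rss),
    call = match.call()
  ), class = "cac_fit")

  if (nboot > 0L && !censored) {
    rel <- y / obj$fitted_values - 1
    boots <- vapply(seq_len(nboot), function(b) {
      yb <- pmax(obj$fitted_values * (1 + sample(rel, n, replace = TRUE)), 0)
      cb <- try(fit_cac(titration_curve(curve$concentration, yb),
                        grid_points = grid_points, alpha = alpha)$cac,
                silent = TRUE)
      if (inherits(cb, "try-error") || is.null(cb)) NA_real_ else cb
    }, 0)
    obj$ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  }
  obj
}

#' @export
print.cac_fit <- function(x, ...) {
  if (x$censored) {
    cat("CAC: censored, >= ", format(x$max_dose), " uM (no significant ",
        "aggregation signal)\n", sep = "")
  } else {
    cat("CAC: ", format(x$cac, digits = 4), " uM\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cac_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cac_fit")
}

#' @export
print.summary.cac_fit <- function(x, ...) {
  f <- x$fit
  cat("Two-segment breakpoint regression on log2 concentration\n")
  cat("  doses: ", length(f$data$concentration), " (",
      format(min(f$data$concentration)), "-", format(f$max_dose),
      " uM)\n", sep = "")
  print(f)
  cat("  slopes (per doubling): pre = ",
      format(f$coefficients["slope_pre"], digits = 4), ", post = ",
      format(f$coefficients["slope_post"], digits = 4), "\n", sep = "")
  cat("  RSS = ", format(f$rss, digits = 4), ", slope-increase F-test p = ",
      format(f$p_value, digits = 3), "\n", sep = "")
  if (!is.null(f$ci))
    cat("  bootstrap 95% CI: ", format(f$ci[1], digits = 4), " - ",
        format(f$ci[2], digits = 4), " uM\n", sep = "")
  invisible(x)
}

#' @export
coef.cac_fit <- function(object, ...) object$coefficients

#' @export
fitted.cac_fit <- function(object, ...) object$fitted_values

#' @export
residuals.cac_fit <- function(object, ...)
  object$data$fluorescence - object$fitted_values

#' @export
predict.cac_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
          else newdata$concentration
  l <- log2(conc)
  co <- object$coefficients
  cc <- object$breakpoint_log2
  if (is.na(cc)) {  # censored: single line through the data
    return(co["intercept"] + co["slope_pre"] * l)
  }
  unname(co["intercept"] + co["slope_pre"] * (l - cc) +
           (co["slope_post"] - co["slope_pre"]) * pmax(l - cc, 0))
}

#' @export
plot.cac_fit <- function(x, ...) {
  d <- x$data
  plot(d$concentration, d$fluorescence, log = "x",
       xlab = "concentration (uM)", ylab = "ThT fluorescence (a.u.)",
       pch = 19, ...)
  grid_c <- 2^seq(log2(min(d$concentration)), log2(max(d$concentration)),
                  length.out = 200)
  lines(grid_c, predict(x, data.frame(concentration = grid_c)), col = 2)
  if (!x$censored) abline(v = x$cac, lty = 2, col = 4)
  legend("topleft", bty = "n", legend = if (x$censored)
    paste0("CAC >= ", format(x$max_dose), " uM") else
      paste0("CAC = ", format(x$cac, digits = 4), " uM"))
  invisible(x)
}

#' Fit CACs for a batch of titration curves
#'
#' @param curves a list of [titration_curve()]s, or a data frame with
#'   columns `molecule`, `concentration`, `fluorescence` (split by
#'   molecule)
#' @param ... passed to [fit_cac()]
#' @return a data frame: one row per curve with `molecule`, `cac`,
#'   `censored`, a rendered `cac_label` (censored entries as
#'   `">= <max> uM"`), segment slopes, `rss` and `p_value`
#' @export
batch_cac <- function(curves, ...) {
  if (is.data.frame(curves) && !inherits(curves, "titration_curve")) {
    curves <- lapply(split(curves, curves$molecule), function(d)
      titration_curve(d$concentration, d$fluorescence,
                      molecule = d$molecule[1]))
  }
  if (!length(curves))
    return(data.frame(molecule = character(0), cac = numeric(0),
                      censored = logical(0), cac_label = character(0),
                      slope_pre = numeric(0), slope_post = numeric(0),
                      rss = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(curves, function(tc) {
    f <- fit_cac(tc, ...)
    data.frame(
      molecule = tc$molecule[1],
      cac = f$cac, censored = f$censored,
      cac_label = if (f$censored) paste0(">= ", format(f$max_dose), " uM")
                  else paste0(format(f$cac, digits = 4), " uM"),
      slope_pre = unname(f$coefficients["slope_pre"]),
      slope_post = unname(f$coefficients["slope_post"]),
      rss = f$rss, p_value = f$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
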