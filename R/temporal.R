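#' Spearman correlation screen of the candidate predictors
#'
#' Pairwise Spearman rank correlations among arrival day, fat-free body
#' mass and fuel load, run before the additive model so collinear
#' predictors are caught.  A constant predictor yields `NA` for its pairs,
#' reported as such.
#'
#' @param migrants augmented migrant table (see
#'   [augment_morphometrics()]).
#' @param predictors column names to screen.
#' @param warn_threshold absolute rho above which a warning is emitted.
#' @return symmetric matrix of Spearman rho values.
#' @export
screen_predictors <- function(migrants,
                              predictors = c("ordinal_day",
                                             "fat_free_mass_g",
                                             "fuel_load_g"),
                              warn_threshold = 0.7) {
  stopifnot(is.data.frame(migrants), all(predictors %in% names(migrants)))
  dat <- migrants[stats::complete.cases(migrants[predictors]), predictors,
                  drop = FALSE]
  if (nrow(dat) < 3L)
    stop("insufficient data: need at least 3 complete cases", call. = FALSE)
  rho <- suppressWarnings(stats::cor(dat, method = "spearman"))
  for (j in seq_along(predictors))
    if (stats::sd(dat[[j]]) == 0) {
      rho[j, ] <- NA_real_; rho[, j] <- NA_real_; rho[j, j] <- 1
    }
  off <- abs(rho[upper.tri(rho)])
  if (any(off > warn_threshold, na.rm = TRUE))
    warning(sprintf("predictor pair(s) with |rho| > %.2f detected",
                    warn_threshold), call. = FALSE)
  rho
}

#' Additive mixed model of natal latitude on arrival day and condition
#'
#' Fits a generalized additive mixed model with the assigned natal
#' latitude (centroid latitude) as response, penalized-spline smooths of
#' arrival ordinal day, fat-free body mass and fuel load, and a random
#' intercept for year.  With fewer than two observed years the random
#' factor is dropped with a notice.  The direction of each smooth is the
#' sign of the slope of an OLS line through the fitted smooth evaluated
#' across the observed predictor range — a robust monotone summary.
#'
#' @param migrants augmented table with columns `centroid_lat`,
#'   `ordinal_day`, `fat_free_mass_g`, `fuel_load_g`, `year`.
#' @param k smooth basis dimension per term.
#' @param alpha significance level used for the direction call and by
#'   [classify_pattern()].
#' @return an object of class `temporal_fit`: the `mgcv::gam` object plus
#'   a per-term table (`edf`, `F`, `p_value`, `direction`), the year
#'   random-intercept variance, `n`, `alpha` and
#'   `direction_of_arrival_effect`.
#' @export
fit_latitude_model <- function(migrants, k = 5, alpha = 0.05) {
  req <- c("centroid_lat", "ordinal_day", "fat_free_mass_g", "fuel_load_g",
           "year")
  stopifnot(is.data.frame(migrants), all(req %in% names(migrants)))
  dat <- migrants[stats::complete.cases(migrants[req]), req, drop = FALSE]
  dropped <- nrow(migrants) - nrow(dat)
  if (dropped > 0)
    message(sprintf("dropping %d incomplete case(s)", dropped))
  if (nrow(dat) < 20L)
    stop("insufficient data: need at least 20 complete cases", call. = FALSE)
  dat$year_f <- factor(dat$year)
  use_re <- nlevels(dat$year_f) >= 2L
  if (!use_re)
    message("single year observed: fitting fixed effects only")

  terms <- c("ordinal_day", "fat_free_mass_g", "fuel_load_g")
  # constant response: nothing to fit, report a flat null model
  if (stats::sd(dat$centroid_lat) < 1e-12) {
    tab <- data.frame(term = terms, edf = 0, F = 0, p_value = 1,
                      direction = "flat", stringsAsFactors = FALSE)
    return(structure(list(model = NULL, terms = tab, year_variance = 0,
                          n = nrow(dat), alpha = alpha,
                          direction_of_arrival_effect = "flat"),
                     class = "temporal_fit"))
  }

  build_formula <- function(kk) {
    rhs <- paste(sprintf("s(%s, k = %d)", terms, kk), collapse = " + ")
    if (use_re) rhs <- paste(rhs, "+ s(year_f, bs = \"re\")")
    stats::as.formula(paste("centroid_lat ~", rhs))
  }
  fit <- tryCatch(mgcv::gam(build_formula(k), data = dat, method = "REML"),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    message("singular fit; retrying with reduced basis dimension")
    fit <- mgcv::gam(build_formula(max(3, k - 2)), data = dat,
                     method = "REML")
  }
  sm <- summary(fit)
  st <- sm$s.table
  tab <- data.frame(term = terms,
                    edf = st[seq_along(terms), "edf"],
                    F = st[seq_along(terms), "F"],
                    p_value = st[seq_along(terms), "p-value"],
                    stringsAsFactors = FALSE)
  tab$direction <- vapply(seq_along(terms), function(j) {
    smooth_direction(fit, terms[j], dat, alpha = alpha,
                     p_value = tab$p_value[j])
  }, character(1))
  yr_var <- if (use_re) {
    vc <- NULL
    utils::capture.output(vc <- mgcv::gam.vcomp(fit, rescale = TRUE))
    if (is.matrix(vc)) {
      row <- grep("year_f", rownames(vc))
      if (length(row)) vc[row[1], "std.dev"]^2 else 0
    } else 0
  } else 0
  structure(list(model = fit, terms = tab, year_variance = yr_var,
                 n = nrow(dat), alpha = alpha,
                 direction_of_arrival_effect =
                   tab$direction[tab$term == "ordinal_day"]),
            class = "temporal_fit")
}

# Sign of an OLS line through the fitted smooth over the observed
# predictor range; "flat" when the term is not significant at alpha.
smooth_direction <- function(fit, term, dat, alpha, p_value, n_grid = 200) {
  if (!is.finite(p_value) || p_value > alpha) return("flat")
  grid <- dat[rep(1L, n_grid), , drop = FALSE]
  for (v in c("ordinal_day", "fat_free_mass_g", "fuel_load_g"))
    grid[[v]] <- mean(dat[[v]])
  grid[[term]] <- seq(min(dat[[term]]), max(dat[[term]]),
                      length.out = n_grid)
  pred <- stats::predict(fit, newdata = grid, type = "terms")
  colname <- grep(paste0("s\\(", term), colnames(pred), value = TRUE)[1]
  slope <- stats::coef(stats::lm(pred[, colname] ~ grid[[term]]))[2]
  if (!is.finite(slope) || slope == 0) "flat"
  else if (slope > 0) "positive" else "negative"
}

#' @export
print.temporal_fit <- function(x, ...) {
  cat(sprintf("<temporal_fit> n = %d, year random-intercept variance = %.4g deg^2\n",
              x$n, x$year_variance))
  print(x$terms, row.names = FALSE)
  cat(sprintf("arrival-day effect: %s\n", x$direction_of_arrival_effect))
  invisible(x)
}

#' Classify the temporal migration pattern
#'
#' Type 1 (southern populations depart first) corresponds to a significant
#' positive arrival-day effect on natal latitude — later passage implies a
#' more northern origin.  Type 2 is the significant negative mirror;
#' anything else is indeterminate.
#'
#' @param fit a `temporal_fit`.
#' @return one of `"type_1"`, `"type_2"`, `"indeterminate"`.
#' @export
classify_pattern <- function(fit) {
  stopifnot(inherits(fit, "temporal_fit"))
  row <- fit$terms[fit$terms$term == "ordinal_day", ]
  sig <- is.finite(row$p_value) && row$p_value < fit$alpha
  if (sig && row$direction == "positive") "type_1"
  else if (sig && row$direction == "negative") "type_2"
  else "indeterminate"
}

#' Loess phenology plot: natal latitude against arrival day
#'
#' Descriptive companion to the additive model: a scatter of assigned
#' natal latitude on arrival ordinal day with a loess line and an
#' approximate 95% confidence band, drawn per year when several years are
#' present.
#'
#' @param migrants augmented table with `centroid_lat` and `ordinal_day`.
#' @param span loess span.
#' @param file optional path; when given, the plot is written there as an
#'   SVG.
#' @return invisibly, the data frame of loess predictions.
#' @export
plot_phenology <- function(migrants, span = 0.75, file = NULL) {
  stopifnot(all(c("centroid_lat", "ordinal_day") %in% names(migrants)))
  dat <- migrants[order(migrants$ordinal_day), ]
  lo <- stats::loess(centroid_lat ~ ordinal_day, data = dat, span = span)
  pr <- stats::predict(lo, se = TRUE)
  band <- data.frame(ordinal_day = dat$ordinal_day, fit = pr$fit,
                     lower = pr$fit - 1.96 * pr$se.fit,
                     upper = pr$fit + 1.96 * pr$se.fit)
  draw <- function() {
    plot(dat$ordinal_day, dat$centroid_lat, pch = 16,
         col = grDevices::adjustcolor("grey30", 0.6),
         xlab = "arrival ordinal day", ylab = "assigned natal latitude (deg N)")
    graphics::polygon(c(band$ordinal_day, rev(band$ordinal_day)),
                      c(band$lower, rev(band$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(band$ordinal_day, band$fit, col = "steelblue", lwd = 2)
  }
  if (!is.null(file)) {
    grDevices::svg(file); on.exit(grDevices::dev.off()); draw()
  } else draw()
  invisible(band)
}
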