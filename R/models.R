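# Candidate model suite on paired (non-insular x, insular y) points.
#
# All models are Gaussian with maximum-likelihood residual variance
# (sigma2 = RSS / n, not REML), which keeps log-likelihoods — and hence AICc
# — comparable across models whose fixed coefficients differ. The parameter
# count k includes the residual-variance parameter (+1), the convention of
# standard information-criterion model-selection tooling.
#
# Taxon group enters the within-side models as a sum-to-zero fixed effect:
# each group gets a deviation from the global line and the deviations sum to
# zero, so "intercept fixed at 0" constrains the taxon-averaged line, which
# is the only geometrically coherent reading of a one-to-one null model with
# a taxon term.

suite_model_names <- c("null", "semi_null", "linear", "log_transformed",
                       "exp_transformed", "broken_stick")

# -- design-matrix helpers ----------------------------------------------------

taxon_design <- function(taxon_values) {
  lev <- intersect(taxon_groups, unique(taxon_values))
  if (length(lev) < 2) {
    return(list(X = matrix(0, length(taxon_values), 0), levels = lev))
  }
  f <- factor(taxon_values, levels = lev)
  C <- stats::contr.sum(length(lev))
  X <- C[as.integer(f), , drop = FALSE]
  colnames(X) <- paste0("taxon_", lev[-length(lev)])
  list(X = X, levels = lev)
}

# OLS via QR; aborts on rank deficiency unless drop_aliased, in which case
# aliased columns get coefficient 0 (used only by the broken-stick refit,
# where a boundary breakpoint can zero out the U column).
ols_fit <- function(X, y, drop_aliased = FALSE) {
  n <- length(y)
  if (ncol(X) == 0) {
    return(list(coef = setNames(numeric(0), character(0)),
                fitted = rep(0, n), residuals = y, rank = 0L))
  }
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coefficients)]
    if (!drop_aliased) {
      abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                   paste(aliased, collapse = ", ")))
    }
    fit$coefficients[is.na(fit$coefficients)] <- 0
  }
  list(coef = setNames(fit$coefficients, colnames(X)),
       fitted = drop(X %*% fit$coefficients),
       residuals = y - drop(X %*% fit$coefficients),
       rank = fit$rank)
}

check_points <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (any(!is.finite(points$x)) || any(!is.finite(points$y))) {
    abort("Paired points must have finite x and y.")
  }
  points
}

new_gd_fit <- function(model, points, coefficients, constraints, residuals,
                       n_free_mean, taxon_levels, side = NULL,
                       converged = TRUE, boundary_flag = FALSE,
                       transform = NULL, psi = NA_real_) {
  n <- nrow(points)
  rss <- sum(residuals^2)
  sigma2 <- rss / n
  # floor the variance inside the likelihood so exact (RSS = 0) fits keep a
  # finite log-likelihood and AICc still separates them by parameter count
  loglik <- -n / 2 * (log(2 * pi * max(sigma2, .Machine$double.xmin)) + 1)
  structure(
    list(
      model = model,
      side = side %||% attr(points, "side") %||%
        (if (!is.null(points[["side"]])) points[["side"]][1] else NA_character_),
      coefficients = coefficients,
      constraints = constraints,
      n = n,
      k = n_free_mean + 1L,
      rss = rss,
      sigma2 = sigma2,
      loglik = loglik,
      converged = converged,
      boundary_flag = boundary_flag,
      transform = transform,
      psi = psi,
      taxon_levels = taxon_levels,
      residuals = residuals,
      data = points
    ),
    class = "gd_fit"
  )
}

#' @export
print.gd_fit <- function(x, ...) {
  cat("<gd_fit> model:", x$model,
      " n:", x$n, " k:", x$k,
      " RSS:", signif(x$rss, 5),
      " logLik:", signif(x$loglik, 6), "\n")
  if (length(x$coefficients) > 0) {
    cat("  coefficients:\n")
    print(round(x$coefficients, 5))
  }
  if (isTRUE(x$boundary_flag)) cat("  [breakpoint at data boundary]\n")
  invisible(x)
}

#' @method tidy gd_fit
#' @export
tidy.gd_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance gd_fit
#' @export
glance.gd_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n = x$n, k = x$k, rss = x$rss, sigma2 = x$sigma2,
    logLik = x$loglik,
    AICc = if (x$n > x$k + 1) aicc(x) else NA_real_,
    converged = x$converged, boundary_flag = x$boundary_flag
  )
}

# Taxon-averaged fitted curve (sum-to-zero coding makes the global
# intercept/slope the taxon-averaged line).
#' Evaluate a fitted model's taxon-averaged curve
#'
#' @param object A `gd_fit`.
#' @param newdata Data frame with column `x` (and optionally `taxon_group`).
#' @param ... Unused.
#' @return Numeric vector of fitted y values.
#' @export
predict.gd_fit <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$data
  x <- newdata$x
  cf <- object$coefficients
  g <- function(name, default = 0) if (name %in% names(cf)) cf[[name]] else default
  base <- switch(
    object$model,
    null = x,
    semi_null = g("slope") * x,
    linear = g("intercept") + g("slope") * x,
    log_transformed = g("intercept") + g("slope") * log(x),
    exp_transformed = g("intercept") + g("slope") * exp(x),
    broken_stick = g("intercept") + g("slope") * x +
      g("slope_change") * pmax(x - object$psi, 0),
    abort(paste0("Unknown model: ", object$model))
  )
  if (!is.null(newdata[["taxon_group"]]) && length(object$taxon_levels) >= 2) {
    lev <- object$taxon_levels
    dev <- setNames(numeric(length(lev)), lev)
    named <- paste0("taxon_", lev[-length(lev)])
    dev[lev[-length(lev)]] <- cf[named]
    dev[lev[length(lev)]] <- -sum(dev[lev[-length(lev)]])
    base <- base + unname(dev[as.character(newdata$taxon_group)])
  }
  unname(base)
}

# -- fitting operations -------------------------------------------------------

#' Fit a (possibly constrained) linear model to paired points
#'
#' Fits `y ~ intercept + slope * x (+ taxon deviations)` by least squares,
#' with either coefficient optionally held fixed: a fixed slope is handled by
#' offsetting the response by `slope_value * x`, a fixed intercept by
#' suppressing the global constant. Both fixed at (0, 1) gives the
#' one-to-one *null* model; intercept fixed at 0 with a free slope gives the
#' *semi-null* (proportional) model; both free gives the *linear* model.
#'
#' @param points Tibble of paired points with columns `x`, `y` and (if
#'   `taxon = TRUE`) `taxon_group`.
#' @param slope,intercept `"free"` or `"fixed"`.
#' @param slope_value,intercept_value Values for fixed coefficients
#'   (defaults 1 and 0: the one-to-one line).
#' @param taxon Include sum-to-zero taxon-group deviations?
#' @return A `gd_fit`.
#' @export
fit_constrained_linear <- function(points,
                                   slope = c("free", "fixed"),
                                   intercept = c("free", "fixed"),
                                   slope_value = 1, intercept_value = 0,
                                   taxon = FALSE) {
  slope <- match.arg(slope)
  intercept <- match.arg(intercept)
  points <- check_points(points)
  n <- nrow(points)

  td <- if (taxon) taxon_design(points$taxon_group) else
    list(X = matrix(0, n, 0), levels = character(0))

  y_adj <- points$y
  if (slope == "fixed") y_adj <- y_adj - slope_value * points$x
  if (intercept == "fixed") y_adj <- y_adj - intercept_value

  cols <- list()
  if (intercept == "free") cols$intercept <- rep(1, n)
  if (slope == "free") cols$slope <- points$x
  X <- cbind(do.call(cbind, cols), td$X)
  if (is.null(X)) X <- matrix(0, n, 0)
  colnames(X) <- c(names(cols), colnames(td$X))

  if (n <= ncol(X)) abort("Too few points for the number of free parameters.")
  fit <- ols_fit(X, y_adj)

  cf <- c(
    intercept = if (intercept == "free") unname(fit$coef[["intercept"]]) else intercept_value,
    slope = if (slope == "free") unname(fit$coef[["slope"]]) else slope_value
  )
  taxon_cf <- fit$coef[grep("^taxon_", names(fit$coef))]
  model <- if (slope == "fixed" && intercept == "fixed") "null"
           else if (intercept == "fixed") "semi_null"
           else if (slope == "fixed") "fixed_slope"
           else "linear"

  new_gd_fit(
    model = model, points = points,
    coefficients = c(cf, taxon_cf),
    constraints = list(slope = slope, intercept = intercept,
                       slope_value = if (slope == "fixed") slope_value else NULL,
                       intercept_value = if (intercept == "fixed") intercept_value else NULL),
    residuals = fit$residuals,
    n_free_mean = ncol(X),
    taxon_levels = td$levels
  )
}

#' Fit a log- or exponential-transformed model
#'
#' Ordinary least squares of y on `log(x)` or `exp(x)` (natural logarithm /
#' exponential), plus taxon deviations if requested. These curved models
#' approximate a threshold (broken-stick) response without estimating a
#' breakpoint; the preprocessing shift to minimum 1 guarantees the log's
#' domain.
#'
#' @inheritParams fit_constrained_linear
#' @param transform `"log"` or `"exp"`.
#' @return A `gd_fit` with model `log_transformed` or `exp_transformed`.
#' @export
fit_transformed <- function(points, transform = c("log", "exp"),
                            taxon = FALSE) {
  transform <- match.arg(transform)
  points <- check_points(points)
  n <- nrow(points)
  tx <- if (transform == "log") {
    if (any(points$x <= 0)) {
      abort("log model requires positive x; shift the data first (shift_to_unit_min).")
    }
    log(points$x)
  } else {
    out <- exp(points$x)
    if (any(!is.finite(out))) {
      abort(paste0("exp(x) overflow at x = ",
                   max(points$x[!is.finite(out)]),
                   "; standardize the data first."))
    }
    out
  }
  td <- if (taxon) taxon_design(points$taxon_group) else
    list(X = matrix(0, n, 0), levels = character(0))
  X <- cbind(intercept = rep(1, n), slope = tx, td$X)
  if (n <= ncol(X)) abort("Too few points for the number of free parameters.")
  fit <- ols_fit(X, points$y)

  new_gd_fit(
    model = paste0(transform, "_transformed"), points = points,
    coefficients = fit$coef,
    constraints = list(slope = "free", intercept = "free"),
    residuals = fit$residuals,
    n_free_mean = ncol(X),
    taxon_levels = td$levels,
    transform = transform
  )
}

#' Fit a broken-stick (segmented) model by iterative linearization
#'
#' Piecewise-linear model with one estimated breakpoint psi: below psi the
#' mean is `intercept + slope * x`; above, the slope changes by
#' `slope_change`. Fitting follows the classic iterative-linearization
#' scheme: at each iteration y is regressed on
#' `{1, x, U = (x − psi)⁺, V = −1[x > psi], taxon}` and psi is updated by
#' `psi + coef(V)/coef(U)` until the step is below `tol`. When the slope
#' change is numerically zero the update is undefined; fitting restarts from
#' the 0.25/0.5/0.75 x-quantiles, and if every restart fails — or the final
#' breakpoint sits within a guard band of the data boundary — the fit is
#' flagged `boundary_flag = TRUE`, meaning segmentation does not improve on
#' a straight line.
#'
#' @inheritParams fit_constrained_linear
#' @param init_psi Initial breakpoint; defaults to the median of x.
#' @param tol Convergence tolerance on the breakpoint step.
#' @param max_iter Maximum iterations per start.
#' @param guard Boundary guard band as a fraction of the x-range.
#' @return A `gd_fit` with model `broken_stick`, breakpoint in `$psi`.
#' @export
fit_broken_stick <- function(points, taxon = FALSE, init_psi = NULL,
                             tol = 1e-6, max_iter = 100, guard = 0.02) {
  points <- check_points(points)
  n <- nrow(points)
  if (n < 6) abort("Broken-stick fitting needs at least 6 points.")
  x <- points$x
  y <- points$y
  rng <- range(x)
  if (diff(rng) == 0) abort("x is constant; no breakpoint exists.")

  td <- if (taxon) taxon_design(points$taxon_group) else
    list(X = matrix(0, n, 0), levels = character(0))

  run_from <- function(psi) {
    h <- 1          # step damping; halved when the update oscillates
    prev_step <- NA_real_
    recent <- rep(NA_real_, 5)  # psi history; kinks can induce tiny cycles
    for (iter in seq_len(max_iter)) {
      U <- pmax(x - psi, 0)
      V <- -as.numeric(x > psi)
      X <- cbind(intercept = 1, slope = x, U = U, V = V, td$X)
      fit <- tryCatch(ols_fit(X, y), error = function(e) NULL)
      if (is.null(fit)) return(list(ok = FALSE))
      bU <- fit$coef[["U"]]
      bV <- fit$coef[["V"]]
      if (!is.finite(bU) || abs(bU) < 1e-10) return(list(ok = FALSE))
      step <- bV / bU
      if (is.finite(prev_step) && sign(step) != sign(prev_step)) h <- h / 2
      prev_step <- step
      psi_new <- psi + h * step
      if (!is.finite(psi_new) || psi_new <= rng[1] || psi_new >= rng[2]) {
        return(list(ok = FALSE, psi = psi_new, diverged = TRUE))
      }
      recent <- c(recent[-1], psi_new)
      settled <- all(is.finite(recent)) &&
        max(recent) - min(recent) < tol * 10
      if (abs(h * step) < tol || settled) {
        return(list(ok = TRUE, psi = psi_new, converged = TRUE))
      }
      psi <- psi_new
    }
    list(ok = TRUE, psi = psi, converged = FALSE)
  }

  # the RSS profile over psi is piecewise smooth with possibly several local
  # minima; run every start and keep the candidate with the lowest refit RSS
  starts <- unique(c(init_psi %||% stats::median(x),
                     unname(quantile(x, c(0.25, 0.5, 0.75)))))
  starts <- starts[starts > rng[1] & starts < rng[2]]
  refit_rss <- function(psi) {
    X <- cbind(1, x, pmax(x - psi, 0), td$X)
    f <- tryCatch(ols_fit(X, y, drop_aliased = TRUE),
                  error = function(e) NULL)
    if (is.null(f)) Inf else sum(f$residuals^2)
  }
  result <- NULL
  for (s in starts) {
    r <- run_from(s)
    if (isTRUE(r$ok)) {
      r$rss <- refit_rss(r$psi)
      if (is.null(result) || r$rss < result$rss) result <- r
    }
  }

  boundary <- FALSE
  converged <- FALSE
  if (is.null(result)) {
    # no interior breakpoint improves on a straight line
    boundary <- TRUE
    psi <- rng[1]
  } else {
    psi <- result$psi
    converged <- isTRUE(result$converged)
    band <- guard * diff(rng)
    if (psi - rng[1] < band || rng[2] - psi < band || !converged) {
      boundary <- TRUE
    }
  }

  # final refit at the chosen breakpoint, without the linearization term V;
  # a boundary psi can alias U with x, in which case U drops to zero and the
  # fit collapses to the straight line (hence never worse than it)
  U <- pmax(x - psi, 0)
  X <- cbind(intercept = 1, slope = x, slope_change = U, td$X)
  if (n <= ncol(X) + 1) abort("Too few points for the broken-stick fit.")
  fit <- ols_fit(X, y, drop_aliased = TRUE)

  new_gd_fit(
    model = "broken_stick", points = points,
    coefficients = c(fit$coef, psi = psi),
    constraints = list(slope = "free", intercept = "free"),
    residuals = fit$residuals,
    n_free_mean = ncol(X) + 1L,  # +1: the breakpoint itself is estimated
    taxon_levels = td$levels,
    converged = converged,
    boundary_flag = boundary,
    psi = psi
  )
}

#' Fit the full candidate model suite for one analysis side
#'
#' Within-population side: one-to-one null, semi-null, linear, log- and
#' exp-transformed, and broken-stick models, all with taxon-group
#' deviations. Among-population side: the same minus the log model and
#' without taxon terms.
#'
#' @inheritParams fit_constrained_linear
#' @param side `"within"` or `"among"`.
#' @param taxon Include taxon deviations; defaults to `TRUE` on the within
#'   side, `FALSE` on the among side.
#' @param ... Passed to [fit_broken_stick()].
#' @return Named list of `gd_fit` objects.
#' @export
fit_model_suite <- function(points, side = c("within", "among"),
                            taxon = NULL, ...) {
  side <- match.arg(side)
  taxon <- taxon %||% (side == "within")
  points <- check_points(points)

  fits <- list(
    null = fit_constrained_linear(points, slope = "fixed",
                                  intercept = "fixed", taxon = taxon),
    semi_null = fit_constrained_linear(points, slope = "free",
                                       intercept = "fixed", taxon = taxon),
    linear = fit_constrained_linear(points, slope = "free",
                                    intercept = "free", taxon = taxon)
  )
  if (side == "within") {
    fits$log_transformed <- fit_transformed(points, "log", taxon = taxon)
  }
  fits$exp_transformed <- fit_transformed(points, "exp", taxon = taxon)
  fits$broken_stick <- fit_broken_stick(points, taxon = taxon, ...)
  for (nm in names(fits)) fits[[nm]]$side <- side
  fits
}

# -- information criteria -----------------------------------------------------

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = 2k − 2 logLik + 2k(k+1)/(n − k − 1)`, where k counts all
#' estimated parameters including the residual variance.
#'
#' @param fit A `gd_fit`.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "gd_fit"))
  n <- fit$n
  k <- fit$k
  if (n <= k + 1) {
    abort(sprintf("AICc undefined: n = %d <= k + 1 = %d.", n, k + 1))
  }
  2 * k - 2 * fit$loglik + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc (or delta-AICc) values
#'
#' `w_i = exp(−Δ_i / 2) / Σ_j exp(−Δ_j / 2)` with Δ referenced to the
#' minimum; invariant to adding a constant to every value.
#'
#' @param aicc_values Numeric vector of AICc (or ΔAICc) values.
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Rank a set of fitted models by AICc
#'
#' Computes AICc, ΔAICc (referenced to the best model) and Akaike weights
#' for fits of the same data. The evidence ratio between two models — "model
#' A preferred N times over model B" — is the ratio of their weights,
#' available via [evidence_ratio()].
#'
#' @param fits Named list of `gd_fit` objects fitted to identical points.
#' @return A `gd_comparison`: list with `table` (tibble sorted by ΔAICc:
#'   model, k, n, logLik, aicc, delta_aicc, weight, boundary_flag) and the
#'   `fits`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2, all(purrr::map_lgl(fits, inherits, "gd_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- purrr::map_chr(fits, "model")
  }
  key <- function(f) digest_points(f$data)
  keys <- purrr::map_chr(fits, key)
  if (length(unique(keys)) != 1) {
    abort("Models were fitted to different point sets; AICc not comparable.")
  }
  a <- purrr::map_dbl(fits, aicc)
  delta <- a - min(a)
  w <- akaike_weights(a)
  tab <- tibble::tibble(
    model = names(fits),
    side = purrr::map_chr(fits, ~ .x$side %||% NA_character_),
    k = purrr::map_int(fits, "k"),
    n = purrr::map_int(fits, "n"),
    logLik = purrr::map_dbl(fits, "loglik"),
    aicc = unname(a),
    delta_aicc = unname(delta),
    weight = unname(w),
    boundary_flag = purrr::map_lgl(fits, ~ isTRUE(.x$boundary_flag))
  ) |>
    dplyr::arrange(.data$delta_aicc)
  structure(list(table = tab, fits = fits), class = "gd_comparison")
}

digest_points <- function(points) {
  o <- order(points$x, points$y)
  paste(signif(points$x[o], 12), signif(points$y[o], 12), collapse = ";")
}

#' @export
print.gd_comparison <- function(x, ...) {
  cat("<gd_comparison> ", nrow(x$table), " models, n = ",
      x$table$n[1], " points\n", sep = "")
  print(dplyr::mutate(x$table, dplyr::across(dplyr::where(is.numeric),
                                             ~ signif(.x, 4))))
  invisible(x)
}

#' @method tidy gd_comparison
#' @export
tidy.gd_comparison <- function(x, ...) x$table

#' @method glance gd_comparison
#' @export
glance.gd_comparison <- function(x, ...) {
  best <- x$table$model[1]
  tibble::tibble(
    n_models = nrow(x$table),
    best_model = best,
    best_weight = x$table$weight[1],
    n = x$table$n[1]
  )
}

#' Evidence ratio between two models
#'
#' @param comparison A `gd_comparison`.
#' @param model_a,model_b Model names as in the comparison table.
#' @return `weight(model_a) / weight(model_b)`.
#' @export
evidence_ratio <- function(comparison, model_a, model_b) {
  stopifnot(inherits(comparison, "gd_comparison"))
  tab <- comparison$table
  get_w <- function(m) {
    i <- match(m, tab$model)
    if (is.na(i)) abort(paste0("Model not in comparison: ", m))
    tab$weight[i]
  }
  get_w(model_a) / get_w(model_b)
}
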