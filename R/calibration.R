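# Calibration of probe readouts against reference GUVs of known cholesterol
# content: weighted linear fit readout = c + m * mol%, inversion
# x_hat = (y - c)/m for unknown vesicles, and first-order (delta-method)
# error propagation combining the readout SEM with the fit uncertainties.

#' Fit a linear calibration of readout versus mol% cholesterol
#'
#' Weighted least squares of `readout_mean ~ chol_molpct` with weights
#' 1/SD^2 (default, matching a fit of condition means with per-condition
#' scatter) or equal weights (ordinary least squares).  Standard errors are
#' scaled by the residual reduced chi-squared, as `stats::lm` (and common
#' fitting software) does.
#'
#' @param points data.frame with columns `chol_molpct` (mol%, in `[0, 100]`),
#'   `readout_mean`, `readout_sd` and optionally `n_vesicles`.
#' @param weighting `"invvar"` (weights 1/SD^2) or `"equal"`.
#' @param modality label stored in the model (`"GP"` or `"lifetime"`).
#' @return an object of class `calibration_model`: `intercept`, `slope`,
#'   `se_intercept`, `se_slope`, `cov` (2x2 parameter covariance),
#'   `weighting`, `sigma` (residual scatter), `n_points`, `modality`.
#' @export
fit_calibration <- function(points, weighting = c("invvar", "equal"),
                            modality = NA_character_) {
  weighting <- match.arg(weighting)
  req <- c("chol_molpct", "readout_mean", "readout_sd")
  if (!all(req %in% names(points)))
    stop("points must have columns ", paste(req, collapse = ", "))
  if (any(points$chol_molpct < 0 | points$chol_molpct > 100))
    stop("chol_molpct must lie in [0, 100]")
  if (any(points$readout_sd < 0)) stop("readout_sd must be >= 0")
  x <- points$chol_molpct
  if (length(unique(x)) < 2)
    stop("calibration requires at least two distinct cholesterol levels")
  if (nrow(points) == 2)
    warning("only two calibration points: zero residual degrees of freedom")
  if (nrow(points) < 2) stop("at least two calibration points required")
  if (weighting == "invvar" && any(points$readout_sd == 0))
    stop("readout_sd of zero is incompatible with inverse-variance ",
         "weighting; use weighting = \"equal\"")
  fit <- if (weighting == "invvar") {
    lm(readout_mean ~ chol_molpct, data = points,
       weights = 1 / points$readout_sd^2)
  } else {
    lm(readout_mean ~ chol_molpct, data = points)
  }
  cf <- coef(fit)
  V <- vcov(fit)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 se_intercept = sqrt(V[1, 1]), se_slope = sqrt(V[2, 2]),
                 cov = V, weighting = weighting,
                 sigma = summary(fit)$sigma, n_points = nrow(points),
                 modality = modality),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> readout = ",
      sprintf("%.4g (+/- %.2g) + %.4g (+/- %.2g) * mol%%", x$intercept,
              x$se_intercept, x$slope, x$se_slope),
      "  [", x$weighting, " weights, n = ", x$n_points, "]\n", sep = "")
  invisible(x)
}

#' Invert a calibration line
#'
#' @param model a [fit_calibration()] result.
#' @param readout readout value(s) (GP or lifetime in the model's units).
#' @param slope_tol smallest |slope| considered invertible.
#' @return estimated mol% cholesterol, `(readout - intercept) / slope`.
#' @export
invert_calibration <- function(model, readout, slope_tol = 1e-10) {
  stopifnot(inherits(model, "calibration_model"))
  if (abs(model$slope) < slope_tol)
    stop("calibration slope is too close to zero for inversion")
  (readout - model$intercept) / model$slope
}

#' Propagate uncertainty through calibration inversion
#'
#' First-order (delta-method) propagation of `x_hat = (y - c)/m` where the
#' readout uncertainty entering the estimate of a condition mean is
#' sigma_y = SD/sqrt(n):
#' `sigma_x^2 = (sigma_y^2 + se_c^2)/m^2 + x_hat^2 se_m^2/m^2
#'  + 2 x_hat cov(c, m)/m^2`
#' (the intercept-slope covariance of a fitted line is typically negative,
#' so the cross term usually shrinks the variance).
#'
#' @param model a [fit_calibration()] result.
#' @param readout condition mean readout.
#' @param readout_sd per-vesicle SD of the readout in the condition.
#' @param n_vesicles number of vesicles averaged.
#' @param include_cov include the intercept-slope covariance term (default);
#'   `FALSE` reproduces a propagation from quoted parameter errors alone.
#' @return an object of class `cholesterol_estimate`: `chol_molpct` and `se`
#'   plus the variance decomposition (`var_readout`, `var_intercept`,
#'   `var_slope`, `var_cov`) and the inputs.
#' @export
propagate_error <- function(model, readout, readout_sd, n_vesicles,
                            include_cov = TRUE) {
  stopifnot(inherits(model, "calibration_model"))
  if (readout_sd < 0) stop("readout_sd must be >= 0")
  if (n_vesicles < 1) stop("n_vesicles must be >= 1")
  xhat <- invert_calibration(model, readout)
  m2 <- model$slope^2
  sem_y <- readout_sd / sqrt(n_vesicles)
  v_y <- sem_y^2 / m2
  v_c <- model$se_intercept^2 / m2
  v_m <- xhat^2 * model$se_slope^2 / m2
  v_cov <- if (include_cov) 2 * xhat * model$cov[1, 2] / m2 else 0
  v <- v_y + v_c + v_m + v_cov
  if (v < 0) {
    warning("covariance term drove the propagated variance negative; ",
            "reporting the covariance-free sum instead")
    v <- v_y + v_c + v_m
    v_cov <- 0
  }
  structure(list(chol_molpct = xhat, se = sqrt(v),
                 var_readout = v_y, var_intercept = v_c, var_slope = v_m,
                 var_cov = v_cov,
                 inputs = list(readout = readout, readout_sd = readout_sd,
                               n_vesicles = n_vesicles,
                               sem_readout = sem_y,
                               include_cov = include_cov)),
            class = "cholesterol_estimate")
}

#' @export
print.cholesterol_estimate <- function(x, ...) {
  cat("<cholesterol_estimate> ", sprintf("%.2f +/- %.2f mol%%",
                                         x$chol_molpct, x$se), "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric omnibus test of a location difference between two or more
#' groups (rank-based H statistic with tie correction, chi-squared
#' approximation with k - 1 degrees of freedom), via `stats::kruskal.test`.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `H`, `df` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("at least two groups required")
  if (any(lengths(groups) < 1)) stop("every group needs at least one value")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1)
    return(list(H = 0, df = length(groups) - 1, p_value = 1))
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Estimate cholesterol content per experimental condition
#'
#' Groups per-vesicle readout records by condition, inverts each condition's
#' mean readout through the calibration with propagated uncertainty, emits
#' per-vesicle point estimates, and runs a Kruskal-Wallis test of the
#' condition effect on the readouts.  When records from both modalities
#' (`"GP"` and `"lifetime"`) are supplied together with a model per
#' modality, the two methods' sets of per-condition estimates are compared
#' with a Kruskal-Wallis test (the method-agreement check).
#'
#' @param records data.frame with columns `vesicle_id`, `condition`,
#'   `modality`, `value` (one row per vesicle).
#' @param models a single [fit_calibration()] model, or a named list of
#'   models keyed by modality.
#' @return list with `conditions` (per condition and modality: n, mean, sd,
#'   sem readout, estimate, se), `per_vesicle` (per-GUV estimates),
#'   `condition_test` (per modality) and `method_test` (or `NULL`).
#' @export
estimate_conditions <- function(records, models) {
  req <- c("vesicle_id", "condition", "modality", "value")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  records <- records[!is.na(records$value), ]
  if (inherits(models, "calibration_model")) {
    models <- setNames(list(models), unique(records$modality)[1])
  }
  cond_rows <- list()
  per_ves <- list()
  condition_test <- list()
  for (mod in unique(records$modality)) {
    if (is.null(models[[mod]]))
      stop("no calibration model supplied for modality ", mod)
    model <- models[[mod]]
    sub <- records[records$modality == mod, ]
    for (cc in unique(sub$condition)) {
      v <- sub$value[sub$condition == cc]
      n <- length(v)
      mu <- mean(v)
      s <- if (n >= 2) sd(v) else NA_real_
      flagged <- n < 2
      est <- if (flagged) {
        list(chol_molpct = invert_calibration(model, mu), se = NA_real_)
      } else {
        propagate_error(model, mu, s, n)
      }
      cond_rows[[length(cond_rows) + 1]] <- data.frame(
        condition = cc, modality = mod, n_vesicles = n,
        readout_mean = mu, readout_sd = s,
        readout_sem = if (flagged) NA_real_ else s / sqrt(n),
        chol_molpct = est$chol_molpct, se = est$se, flagged = flagged)
      per_ves[[length(per_ves) + 1]] <- data.frame(
        vesicle_id = sub$vesicle_id[sub$condition == cc], condition = cc,
        modality = mod, readout = v,
        chol_molpct = invert_calibration(model, v))
    }
    gl <- split(sub$value, sub$condition)
    condition_test[[mod]] <- if (length(gl) >= 2) kruskal_wallis(gl) else NULL
  }
  conditions <- do.call(rbind, cond_rows)
  method_test <- NULL
  mods <- unique(conditions$modality)
  if (length(mods) == 2) {
    method_test <- kruskal_wallis(split(conditions$chol_molpct,
                                        conditions$modality))
  }
  list(conditions = conditions, per_vesicle = do.call(rbind, per_ves),
       condition_test = condition_test, method_test = method_test)
}
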