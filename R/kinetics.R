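#' Sigmoid model of cell-free expression kinetics
#'
#' Phenomenological model of protein accumulation in a cell-free expression
#' reaction: `y(t) = k' + k * t^n / (t^n + K^n)`, with `k'` the baseline
#' (uM), `k` the final yield (uM), `K` the half-rise time (min) and `n` the
#' steepness. Two derived quantities summarize a fitted model: the plateau
#' time (expression lifespan) `T_plateau = 2K/n + K`, the time at which the
#' tangent at the half-rise point reaches the plateau, and the apparent
#' translation rate `v = k*n/(4K)`, the slope of the curve at `t = K`.
#'
#' @param k_prime baseline concentration, uM.
#' @param k final yield, uM (>= 0).
#' @param K half-rise time, min (> 0).
#' @param n steepness (>= 1).
#' @return A `kinetic_model` object.
#' @export
kinetic_model <- function(k_prime, k, K, n) {
  if (k < 0) stop("k must be >= 0")
  if (K <= 0) stop("K must be > 0")
  if (n < 1) stop("n must be >= 1")
  structure(list(k_prime = k_prime, k = k, K = K, n = n),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf(paste0("kinetic_model: k' = %.4g uM, k = %.4g uM, ",
                     "K = %.4g min, n = %.4g\n"), x$k_prime, x$k, x$K, x$n))
  cat(sprintf("  T_plateau = %.4g min, v_translation = %.4g uM/min\n",
              plateau_time(x), translation_rate(x)))
  invisible(x)
}

#' @rdname kinetic_model
#' @param t time, min (>= 0); vectorized.
#' @param model a `kinetic_model`.
#' @return `sigmoid_conc()` returns the model concentration at `t`, uM.
#' @export
sigmoid_conc <- function(t, model) {
  stopifnot(inherits(model, "kinetic_model"))
  if (any(t < 0)) stop("t must be >= 0")
  tn <- t^model$n
  model$k_prime + model$k * tn / (tn + model$K^model$n)
}

#' @rdname kinetic_model
#' @return `plateau_time()` returns `2K/n + K` in minutes.
#' @export
plateau_time <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  2 * model$K / model$n + model$K
}

#' @rdname kinetic_model
#' @return `translation_rate()` returns `k*n/(4K)` in uM/min.
#' @export
translation_rate <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  model$k * model$n / (4 * model$K)
}

#' Fit the sigmoid expression model to a time course
#'
#' Least-squares fit of the four-parameter sigmoid (optionally weighted by
#' `1/sigma^2` when per-point uncertainties are supplied) using
#' Levenberg-Marquardt with bounds (`n` in \[1, 20\], `K > 0`, `k >= 0`).
#' Starting values follow the shape of the data (baseline = min, amplitude =
#' range, `K` = time of half rise, `n` = 4) and the fit is restarted from
#' five deterministic jitters of (`K`, `n`) to guard against the flat
#' direction in `n`; the restart with the lowest residual sum of squares is
#' kept.
#'
#' @param time time points, min.
#' @param y measured concentrations, uM.
#' @param sigma optional per-point SDs for weighting.
#' @return list with `model` ([kinetic_model]), `converged`, `boundary`
#'   (`TRUE` when the steepness ended on a box constraint, flagging an
#'   unreliable fit), `resid_sd`, `vcov` (parameter covariance), and `fit`
#'   (the underlying nls object).
#' @export
fit_sigmoid <- function(time, y, sigma = NULL) {
  stopifnot(length(time) == length(y))
  if (length(y) < 5L) stop("need at least 5 points spanning rise and plateau")
  if (diff(range(y)) == 0) stop("all responses equal: nothing to fit")
  if (!is.null(sigma)) stopifnot(length(sigma) == length(y), all(sigma > 0))
  kp0 <- min(y); k0 <- diff(range(y))
  half <- kp0 + k0 / 2
  ord <- order(time)
  K0 <- approx(cummax(y[ord]), time[ord], xout = half, ties = "ordered",
               rule = 2)$y
  K0 <- max(K0, min(time[time > 0], na.rm = TRUE) / 2, 1e-3)
  jit <- list(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.5), c(1, 2))
  w <- if (is.null(sigma)) NULL else 1 / sigma^2
  df <- data.frame(t = time, y = y)
  best <- NULL
  for (j in jit) {
    st <- list(kp = kp0, k = k0, K = K0 * j[1L], n = clamp(4 * j[2L], 1, 20))
    args <- list(y ~ kp + k * t^n / (t^n + K^n), data = df, start = st,
                 lower = c(kp = -Inf, k = 0, K = 1e-6, n = 1),
                 upper = c(kp = Inf, k = Inf, K = Inf, n = 20),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- w
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("sigmoid fit did not converge")
  cf <- coef(best$fit)
  list(model = kinetic_model(cf[["kp"]], cf[["k"]], cf[["K"]], cf[["n"]]),
       converged = best$fit$convInfo$isConv,
       # a steepness pinned at its box constraint is not an interior
       # optimum; derived quantities from such fits should be treated
       # with caution (and are excluded from recovery medians)
       boundary = cf[["n"]] <= 1 + 1e-6 || cf[["n"]] >= 20 - 1e-6,
       resid_sd = sd(stats::resid(best$fit)),
       vcov = tryCatch(vcov(best$fit), error = function(e) NULL),
       fit = best$fit)
}

#' Variance-weighted calibration curve
#'
#' Fits intensity as a linear function of concentration by weighted least
#' squares with instrumental variance weighting, `w_i = 1 / sigma_i^2`,
#' where `sigma_i` is the replicate SD at calibration level `i`. Levels with
#' non-positive SD are assigned the smallest positive SD in the set and
#' flagged.
#'
#' @param conc calibration concentrations, uM (>= 3 distinct levels).
#' @param intensity mean intensity per level.
#' @param sigma per-level intensity SD.
#' @return A `calibration_curve`: list with `slope`, `intercept`, `weights`,
#'   `conc_range`, `sigma_replaced` flag vector and the underlying `lm` fit.
#' @export
fit_calibration <- function(conc, intensity, sigma) {
  stopifnot(length(conc) == length(intensity), length(conc) == length(sigma))
  if (length(conc) < 3L) stop("need at least 3 calibration levels")
  replaced <- !(sigma > 0) | !is.finite(sigma)
  if (all(replaced)) stop("no valid (positive) calibration SDs")
  sigma[replaced] <- min(sigma[!replaced])
  w <- 1 / sigma^2
  fit <- lm(intensity ~ conc, weights = w)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 sigma = sigma, weights = w, conc_range = range(conc),
                 sigma_replaced = replaced, fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: intensity = %.4g * conc + %.4g (%g-%g uM)\n",
              x$slope, x$intercept, x$conc_range[1L], x$conc_range[2L]))
  invisible(x)
}

#' Quantify a peptide from a calibration curve
#'
#' Converts a measured peak intensity to concentration through the inverse
#' calibration map, after optional normalization by the internal-standard
#' ratio (a constitutive peptide measured in the same run) and correction
#' for sample dilution:
#' `conc = dilution * (intensity / is_ratio - intercept) / slope`.
#' Concentrations whose back-calculated level falls outside the calibrated
#' range are flagged as extrapolated.
#'
#' @param intensity measured peak intensity.
#' @param curve a `calibration_curve` with positive slope.
#' @param dilution dilution factor applied to the sample (1 = none).
#' @param is_ratio optional internal-standard normalization ratio.
#' @param peptide optional peptide identifier carried through.
#' @return list with `concentration_uM`, `extrapolated`, `dilution`,
#'   `is_normalized`, `peptide`.
#' @export
quantify_peptide <- function(intensity, curve, dilution = 1,
                             is_ratio = NULL, peptide = NA_character_) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive")
  if (!is.null(is_ratio)) intensity <- intensity / is_ratio
  level <- (intensity - curve$intercept) / curve$slope
  list(concentration_uM = dilution * level,
       extrapolated = level < curve$conc_range[1L] |
         level > curve$conc_range[2L],
       dilution = dilution, is_normalized = !is.null(is_ratio),
       peptide = peptide)
}

#' Protein concentration from peptide quantifications
#'
#' Reports the protein concentration as that of the most C-terminal
#' quantified peptide (the peptide whose sequence position ends last), since
#' only ribosomes that completed translation produce it. A warning is issued
#' when peptide coverage stops well short of the C-terminus (the chosen
#' peptide ends before `coverage_warn` of the protein length), in which case
#' the value is an upper-bound proxy rather than a full-length measurement.
#'
#' @param peptides data.frame with columns `peptide`, `end` (last residue
#'   position) and `concentration_uM`.
#' @param protein_length protein length in residues.
#' @param coverage_warn fraction of `protein_length` below which a coverage
#'   warning is raised.
#' @return list with `concentration_uM`, `peptide`, `end`, `coverage_ok`.
#' @export
protein_concentration <- function(peptides, protein_length,
                                  coverage_warn = 0.9) {
  stopifnot(all(c("peptide", "end", "concentration_uM") %in% names(peptides)),
            nrow(peptides) >= 1L)
  i <- which.max(peptides$end)
  ok <- peptides$end[i] >= coverage_warn * protein_length
  if (!ok)
    warning("most C-terminal quantified peptide ends at residue ",
            peptides$end[i], " of ", protein_length,
            ": concentration may not reflect full-length protein")
  list(concentration_uM = peptides$concentration_uM[i],
       peptide = peptides$peptide[i], end = peptides$end[i],
       coverage_ok = ok)
}
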