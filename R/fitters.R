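# Nonlinear least-squares fitters for the three modalities. All affinity
# and rate parameters are fit in log-space (positivity by construction) via
# Levenberg-Marquardt (minpack.lm::nls.lm), with multi-start initialization;
# standard errors come from the fit covariance and map back through the
# delta method (se(theta) = theta * se(log theta)).

# run nls.lm from several starts, keep the best SSE (ties: smallest first
# parameter, i.e. smallest kd/kon)
.multi_start_lm <- function(residual_fn, starts, lower = NULL, upper = NULL) {
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = residual_fn,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- fit$deviance
    if (is.null(best) || sse < best$deviance * (1 - 1e-10) ||
        (abs(sse - best$deviance) <= 1e-10 * max(sse, 1) && fit$par[[1]] < best$par[[1]])) {
      best <- fit
    }
  }
  if (is.null(best)) abort("Nonlinear fit failed to converge from any start.")
  best
}

.lm_se <- function(fit) {
  s <- tryCatch(summary(fit), error = function(e) NULL)
  if (is.null(s)) return(rep(NA_real_, length(fit$par)))
  s$coefficients[, "Std. Error"]
}

#' Fit an equilibrium binding isotherm
#'
#' Nonlinear least squares of the 1:1 Langmuir isotherm
#' [equilibrium_response()] to concentration-response data, replicate-aware.
#' Kd and Rmax are fit in log-space with multi-start initialization (Kd
#' starts on a log-grid around the geometric mean of the concentrations;
#' Rmax at 1.2x the maximum response). Warns when the concentration series
#' does not bracket the fitted Kd, since the Kd is then poorly constrained
#' (wide standard error).
#'
#' @param data Tibble/data frame with columns `conc` (molar) and `response`
#'   (RU or Rmax-normalized), optionally `replicate`.
#' @param normalize_to_rmax If `TRUE`, responses are treated as already
#'   normalized and Rmax is still estimated (near 1).
#' @return An `equilibrium_fit` with `kd`, `kd_se`, `rmax`, `rmax_se`,
#'   `sse`, `converged`, and the data; see [tidy()]/[glance()]/[autoplot()].
#' @export
fit_equilibrium <- function(data, normalize_to_rmax = FALSE) {
  data <- tibble::as_tibble(data)
  if (!all(c("conc", "response") %in% names(data))) {
    abort("`data` needs columns `conc` and `response`.")
  }
  data <- dplyr::filter(data, is.finite(.data$conc), is.finite(.data$response))
  concs <- unique(data$conc[data$conc > 0])
  if (length(concs) < 3L) {
    warn("Fewer than 3 distinct positive concentrations; Kd will be poorly constrained.")
  }
  if (all(data$response == 0)) abort("All responses are zero; nothing to fit.")

  resid_fn <- function(p) {
    data$response - equilibrium_response(data$conc, exp(p[["lkd"]]), exp(p[["lrmax"]]))
  }
  kd0 <- exp(mean(log(concs)))
  rmax0 <- if (normalize_to_rmax) 1 else 1.2 * max(data$response)
  starts <- purrr::map(
    kd0 * 10^seq(-2, 2, by = 1),
    ~ c(lkd = log(.x), lrmax = log(max(rmax0, 1e-6)))
  )
  fit <- .multi_start_lm(resid_fn, starts)
  se <- .lm_se(fit)
  kd <- exp(fit$par[["lkd"]])
  rmax <- exp(fit$par[["lrmax"]])
  if (kd > max(concs) || kd < min(concs)) {
    warn(sprintf(
      "Fitted Kd (%.3g M) lies outside the concentration series [%.3g, %.3g] M; estimate is extrapolated.",
      kd, min(concs), max(concs)
    ))
  }
  structure(
    list(
      kd = kd, kd_se = kd * se[[1]],
      rmax = rmax, rmax_se = rmax * se[[2]],
      sse = fit$deviance,
      converged = fit$info %in% 1:4,
      n = nrow(data),
      data = data
    ),
    class = "equilibrium_fit"
  )
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  cat(sprintf(
    "1:1 equilibrium fit: Kd = %s +/- %s, Rmax = %.3g (SSE %.3g, n = %d)\n",
    format_kd(x$kd), format_kd(x$kd_se), x$rmax, x$sse, x$n
  ))
  invisible(x)
}

#' @export
#' @method tidy equilibrium_fit
tidy.equilibrium_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "rmax"),
    estimate = c(x$kd, x$rmax),
    std.error = c(x$kd_se, x$rmax_se)
  )
}

#' @export
#' @method glance equilibrium_fit
glance.equilibrium_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = x$n, converged = x$converged)
}

#' Fit 1:1 binding kinetics to SPR sensorgrams
#'
#' Global least squares of the association + dissociation 1:1 Langmuir model
#' over one or more concentrations, sharing kon and koff with a per-curve
#' Rmax. All parameters are fit in log-space; initialization runs a 5x5
#' log-grid of (kon, koff) starts and keeps the best SSE. A single-curve fit
#' is permitted with a warning (kon and Rmax are then strongly correlated).
#'
#' @param data Tibble with columns `time` (s, measured from the start of
#'   each phase), `response` (RU), `conc` (molar), `phase` (`"assoc"` or
#'   `"dissoc"`).
#' @param kon_grid,koff_grid Log-spaced start grids for the rate constants.
#' @return A `kinetic_fit` with `kon`, `koff` (and SEs), per-curve `rmax`,
#'   `kd` via [kd_from_kinetics()], `sse`, `converged`.
#' @export
fit_kinetics <- function(data,
                         kon_grid = 10^seq(3, 7, length.out = 5),
                         koff_grid = 10^seq(-3, 1, length.out = 5)) {
  data <- tibble::as_tibble(data)
  need <- c("time", "response", "conc", "phase")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (!all(data$phase %in% c("assoc", "dissoc"))) {
    abort("`phase` must be 'assoc' or 'dissoc'.")
  }
  concs <- sort(unique(data$conc))
  if (length(concs) < 2L) {
    warn("Kinetic fit from a single concentration; kon and Rmax are poorly separable.")
  }
  assoc <- dplyr::filter(data, .data$phase == "assoc")
  t_end <- vapply(concs, function(cc) max(assoc$time[assoc$conc == cc]), numeric(1))
  names(t_end) <- as.character(concs)

  conc_idx <- match(data$conc, concs)
  is_assoc <- data$phase == "assoc"
  t_end_row <- t_end[conc_idx]
  model_responses <- function(kon, koff, rmax_vec) {
    rmax_row <- rmax_vec[conc_idx]
    kobs <- kon * data$conc + koff
    req <- rmax_row * data$conc * kon / kobs
    r_end <- req * (1 - exp(-kobs * t_end_row))
    ifelse(is_assoc,
           req * (1 - exp(-kobs * data$time)),
           r_end * exp(-koff * data$time))
  }
  resid_fn <- function(p) {
    data$response - model_responses(
      exp(p[["lkon"]]), exp(p[["lkoff"]]),
      exp(p[grep("^lrmax", names(p))])
    )
  }
  rmax0 <- max(data$response) * 1.2
  grid <- expand.grid(kon = kon_grid, koff = koff_grid)
  starts <- purrr::map2(grid$kon, grid$koff, function(k1, k2) {
    c(
      lkon = log(k1), lkoff = log(k2),
      setNames(rep(log(max(rmax0, 1e-6)), length(concs)),
               paste0("lrmax", seq_along(concs)))
    )
  })
  fit <- .multi_start_lm(resid_fn, starts)
  se <- .lm_se(fit)
  kon <- exp(fit$par[["lkon"]])
  koff <- exp(fit$par[["lkoff"]])
  rmax <- setNames(exp(fit$par[grep("^lrmax", names(fit$par))]), as.character(concs))
  kd <- kd_from_kinetics(kon, koff, kon * se[[1]], koff * se[[2]])
  structure(
    list(
      kon = kon, kon_se = kon * se[[1]],
      koff = koff, koff_se = koff * se[[2]],
      rmax = rmax,
      kd = kd$kd, kd_se = kd$kd_se,
      sse = fit$deviance,
      converged = fit$info %in% 1:4,
      n = nrow(data),
      t_end = t_end,
      data = data
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "1:1 kinetic fit: kon = %.3g +/- %.2g /(M s), koff = %.3g +/- %.2g /s, Kd = %s\n",
    x$kon, x$kon_se, x$koff, x$koff_se, format_kd(x$kd)
  ))
  invisible(x)
}

#' @export
#' @method tidy kinetic_fit
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kon", "koff", "kd", paste0("rmax_", names(x$rmax))),
    estimate = c(x$kon, x$koff, x$kd, unname(x$rmax)),
    std.error = c(x$kon_se, x$koff_se, x$kd_se, rep(NA_real_, length(x$rmax)))
  )
}

#' @export
#' @method glance kinetic_fit
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = x$n, converged = x$converged,
                 n_concentrations = length(x$rmax))
}

#' Fit a fluorescence-anisotropy titration
#'
#' Least squares of `signal = s_free + (s_bound - s_free) * f`, where `f` is
#' the exact 1:1 depletion solution [fraction_bound()] at the fixed labeled
#' concentration. Kd is fit in log-space; the endpoint signals are linear
#' parameters. A titration with no curvature (essentially constant signal)
#' is rejected.
#'
#' @param data Tibble with columns `protein_conc` (molar) and `signal`.
#' @param labeled_conc Fixed labeled-peptide concentration, molar.
#' @return An `anisotropy_fit` with `kd`, `kd_se`, `s_free`, `s_bound`.
#' @export
fit_anisotropy <- function(data, labeled_conc) {
  data <- tibble::as_tibble(data)
  if (!all(c("protein_conc", "signal") %in% names(data))) {
    abort("`data` needs columns `protein_conc` and `signal`.")
  }
  stopifnot_scalar_number(labeled_conc, "labeled_conc")
  rng <- diff(range(data$signal))
  if (rng <= 1e-12 || rng < 1e-3 * max(abs(data$signal), 1e-12)) {
    abort("Signal is constant across the titration; Kd is unidentifiable.")
  }
  resid_fn <- function(p) {
    f <- fraction_bound(data$protein_conc, labeled_conc, exp(p[["lkd"]]))
    data$signal - (p[["s_free"]] + (p[["s_bound"]] - p[["s_free"]]) * f)
  }
  pc <- unique(data$protein_conc[data$protein_conc > 0])
  kd0 <- exp(mean(log(pc)))
  s_lo <- min(data$signal); s_hi <- max(data$signal)
  starts <- purrr::map(
    kd0 * 10^seq(-2, 2, by = 1),
    ~ c(lkd = log(.x), s_free = s_lo, s_bound = s_hi)
  )
  fit <- .multi_start_lm(resid_fn, starts)
  se <- .lm_se(fit)
  kd <- exp(fit$par[["lkd"]])
  structure(
    list(
      kd = kd, kd_se = kd * se[[1]],
      s_free = fit$par[["s_free"]], s_bound = fit$par[["s_bound"]],
      labeled_conc = labeled_conc,
      sse = fit$deviance,
      converged = fit$info %in% 1:4,
      n = nrow(data),
      data = data
    ),
    class = "anisotropy_fit"
  )
}

#' @export
print.anisotropy_fit <- function(x, ...) {
  cat(sprintf(
    "Anisotropy titration fit: Kd = %s +/- %s (L = %s, SSE %.3g)\n",
    format_kd(x$kd), format_kd(x$kd_se), format_kd(x$labeled_conc), x$sse
  ))
  invisible(x)
}

#' @export
#' @method tidy anisotropy_fit
tidy.anisotropy_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "s_free", "s_bound"),
    estimate = c(x$kd, x$s_free, x$s_bound),
    std.error = c(x$kd_se, NA_real_, NA_real_)
  )
}

#' @export
#' @method glance anisotropy_fit
glance.anisotropy_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = x$n, converged = x$converged)
}
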