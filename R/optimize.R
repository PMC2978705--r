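# End-to-end in-silico optimization: enumerate -> screen -> select ->
# characterize -> plan -> predict -> assess.

#' Configuration for an end-to-end optimization run
#'
#' Bundles the tunable parameters of [run_optimization()] with the defaults
#' used throughout the package: a 50 uM single-concentration screen with a
#' 60 s association window, triplicate injections, a 15-fold selection
#' threshold, and triplicate equilibrium-isotherm characterization of the
#' lead, the selected point-variants and the planned combinations.
#'
#' @param alphabet Substitution set for the library.
#' @param positions Library positions (default the whole randomized region).
#' @param mode Enumeration mode (see [enumerate_variants()]).
#' @param screen_conc Screen concentration, molar.
#' @param assoc_time Association window, s.
#' @param screen_replicates Replicate injections in the screen.
#' @param rmax Saturating response, RU.
#' @param screen_noise_sd Screen response noise SD, RU.
#' @param kon_ref Reference on-rate for the screen simulator, 1/(M s).
#' @param fold_threshold Candidate selection threshold.
#' @param adjacency_rule Apply the bulky-adjacency planning rule.
#' @param isotherm_concs Concentration grid for characterization, molar.
#' @param isotherm_replicates Replicates per concentration per fit.
#' @param isotherm_noise_sd Isotherm noise SD, RU.
#' @param n_fits Independent isotherm experiments per peptide (their dG and
#'   Kd estimates are averaged separately).
#' @param assess_subsets Also characterize all sub-combinations (size >= 2)
#'   of the chosen set for the additivity assessment.
#' @param deviation_threshold Absolute flagging floor, kcal/mol.
#' @return A named list of class `optimization_config`.
#' @export
optimization_config <- function(alphabet = c("Y", "A", "D", "S", "K", "N", "V", "W"),
                                positions = NULL,
                                mode = "exclude_identity",
                                screen_conc = 50e-6,
                                assoc_time = 60,
                                screen_replicates = 3,
                                rmax = 100,
                                screen_noise_sd = 2,
                                kon_ref = 1e4,
                                fold_threshold = 15,
                                adjacency_rule = TRUE,
                                isotherm_concs = 10^seq(-6.5, -3.5, length.out = 8),
                                isotherm_replicates = 3,
                                isotherm_noise_sd = 1,
                                n_fits = 3,
                                assess_subsets = TRUE,
                                deviation_threshold = 0) {
  structure(
    list(
      alphabet = alphabet, positions = positions, mode = mode,
      screen_conc = screen_conc, assoc_time = assoc_time,
      screen_replicates = screen_replicates, rmax = rmax,
      screen_noise_sd = screen_noise_sd, kon_ref = kon_ref,
      fold_threshold = fold_threshold, adjacency_rule = adjacency_rule,
      isotherm_concs = isotherm_concs,
      isotherm_replicates = isotherm_replicates,
      isotherm_noise_sd = isotherm_noise_sd, n_fits = n_fits,
      assess_subsets = assess_subsets,
      deviation_threshold = deviation_threshold
    ),
    class = "optimization_config"
  )
}

# characterize one peptide by repeated simulated isotherm experiments; dG
# and Kd replicate estimates are averaged separately
measure_dg <- function(landscape, codes, config, seed) {
  fits <- purrr::map(seq_len(config$n_fits), function(i) {
    iso <- simulate_isotherm(
      landscape, codes,
      concs = config$isotherm_concs,
      rmax = config$rmax,
      noise_sd = config$isotherm_noise_sd,
      replicates = config$isotherm_replicates,
      seed = derive_seed(seed, 100L + i)
    )
    suppressWarnings(fit_equilibrium(iso))
  })
  kds <- vapply(fits, function(f) f$kd, numeric(1))
  kd_ses <- vapply(fits, function(f) f$kd_se, numeric(1))
  dgs <- vapply(kds, function(k) kd_to_dg(k)$dg, numeric(1))
  dg_ses <- vapply(seq_along(fits), function(i) kd_to_dg(kds[i], kd_ses[i])$dg_se, numeric(1))
  kd_agg <- aggregate_replicates(kds, kd_ses)
  dg_agg <- aggregate_replicates(dgs, dg_ses)
  tibble::tibble(
    dg = dg_agg$mean, dg_se = dg_agg$se,
    kd = kd_agg$mean, kd_se = kd_agg$se,
    n_fits = dg_agg$n
  )
}

#' Run the full optimization algorithm on a simulated target
#'
#' Executes the pipeline end to end against a ground-truth landscape:
#' enumerate the point-variant library, screen it at a fixed concentration,
#' build the molecular-weight-adjusted fold-change heat map, select
#' enhancing candidates, measure their free-energy contributions from
#' simulated equilibrium isotherms, plan a combination, predict the
#' combined affinity additively, then characterize the planned combination
#' (and optionally every sub-combination) and assess observed vs predicted
#' additivity. With no enhancing candidates the run stops early and the
#' report says no optimization is possible.
#'
#' @param landscape An [energy_landscape()].
#' @param config An [optimization_config()].
#' @param seed Integer seed for every stochastic stage.
#' @return An `optimization_report` with fields `library`, `screen`, `map`,
#'   `candidates`, `contributions`, `plan`, `prediction`, `additivity`,
#'   `lead`, `config`, `seed`, `message`.
#' @export
run_optimization <- function(landscape, config = optimization_config(), seed = 1L) {
  stopifnot(inherits(landscape, "energy_landscape"))
  stopifnot(inherits(config, "optimization_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  lib <- stage("design", enumerate_variants(
    landscape$lead, alphabet = config$alphabet,
    positions = config$positions %||% seq_len(randomized_length(landscape$lead)),
    mode = config$mode
  ))
  screen <- stage("screen", simulate_screen(
    landscape, lib,
    conc = config$screen_conc, assoc_time = config$assoc_time,
    replicates = config$screen_replicates, rmax = config$rmax,
    noise_sd = config$screen_noise_sd, kon_ref = config$kon_ref,
    seed = derive_seed(seed, 11L)
  ))
  map <- stage("heatmap", fold_change_map(screen))
  candidates <- stage("select", select_enhancing(map, config$fold_threshold))
  report <- list(
    library = lib, screen = screen, map = map, candidates = candidates,
    contributions = NULL, plan = NULL, prediction = NULL, additivity = NULL,
    lead = NULL, config = config, seed = seed, message = NULL
  )
  if (nrow(candidates) == 0L) {
    report$message <- sprintf(
      "No candidates reached the %g-fold threshold: no optimization possible.",
      config$fold_threshold
    )
    return(structure(report, class = "optimization_report"))
  }

  lead_meas <- stage("characterize", measure_dg(landscape, character(0), config,
                                                derive_seed(seed, 21L)))
  contribs <- stage("characterize", {
    meas <- purrr::imap(candidates$variant_code, function(code, i) {
      m <- measure_dg(landscape, code, config, derive_seed(seed, 30L + i))
      rc <- relative_contribution(m$dg, lead_meas$dg, m$dg_se, lead_meas$dg_se)
      tibble::tibble(
        variant_code = code,
        position = candidates$position[i],
        wild = candidates$wild[i],
        sub = candidates$sub[i],
        dg = m$dg, dg_se = m$dg_se, kd = m$kd, kd_se = m$kd_se,
        ddg = rc$ddg, ddg_se = rc$ddg_se
      )
    })
    dplyr::bind_rows(meas)
  })
  plan <- stage("plan", plan_combination(contribs,
                                         adjacency_rule = config$adjacency_rule))
  prediction <- stage("predict", predict_plan(plan, lead_meas$dg, lead_meas$dg_se,
                                              temperature = landscape$temperature))

  chosen <- plan$chosen$variant_code
  subsets <- list(chosen)
  if (config$assess_subsets && length(chosen) > 2L) {
    for (k in 2:(length(chosen) - 1L)) {
      subsets <- c(subsets, utils::combn(chosen, k, simplify = FALSE))
    }
  }
  additivity <- stage("assess", {
    rows <- purrr::imap(subsets, function(codes, i) {
      obs <- measure_dg(landscape, codes, config, derive_seed(seed, 200L + i))
      pred <- combine_additive(
        lead_meas$dg, lead_meas$dg_se,
        dplyr::filter(plan$chosen, .data$variant_code %in% codes),
        temperature = landscape$temperature
      )
      tibble::tibble(
        variant_set = paste(codes, collapse = "+"),
        dg_obs = obs$dg, se_obs = obs$dg_se,
        dg_pred = pred$dg_pred, se_pred = pred$se_pred
      )
    })
    assess_additivity(dplyr::bind_rows(rows),
                      deviation_threshold = config$deviation_threshold)
  })
  report$lead <- lead_meas
  report$contributions <- contribs
  report$plan <- plan
  report$prediction <- prediction
  report$additivity <- additivity
  report$message <- sprintf(
    "Optimized %s: chose %s, predicted Kd %s (range %s - %s).",
    landscape$lead$name, paste(chosen, collapse = "+"),
    format_kd(prediction$kd_center),
    format_kd(prediction$kd_high), format_kd(prediction$kd_low)
  )
  structure(report, class = "optimization_report")
}

#' @export
print.optimization_report <- function(x, ...) {
  cat("Optimization report\n")
  cat(sprintf("  Library: %d point-variants\n", nrow(x$library)))
  cat(sprintf("  Candidates >= threshold: %d\n", nrow(x$candidates)))
  cat(sprintf("  %s\n", x$message))
  if (!is.null(x$additivity)) {
    g <- glance(x$additivity)
    cat(sprintf("  Additivity: OLS slope %.3f, through-origin %.3f, %d flagged\n",
                g$slope_ols, g$slope_origin, g$n_flagged))
  }
  invisible(x)
}

#' @export
#' @method glance optimization_report
glance.optimization_report <- function(x, ...) {
  tibble::tibble(
    n_library = nrow(x$library),
    n_candidates = nrow(x$candidates),
    n_chosen = if (is.null(x$plan)) 0L else nrow(x$plan$chosen),
    dg_pred = if (is.null(x$prediction)) NA_real_ else x$prediction$dg_pred,
    kd_pred = if (is.null(x$prediction)) NA_real_ else x$prediction$kd_center,
    slope_ols = if (is.null(x$additivity)) NA_real_ else x$additivity$slope_ols$estimate %||% NA_real_,
    n_flagged = if (is.null(x$additivity)) NA_integer_ else sum(x$additivity$pairs$flagged)
  )
}
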