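# The optimization pipeline: screen -> heat map -> candidate selection ->
# combination planning -> additive prediction -> observed-vs-predicted
# additivity assessment.

#' Fold-change heat map from a point-variant screen
#'
#' Per-variant screen responses are molecular-weight adjusted (multiplied by
#' `MW_lead / MW_variant`, so that equal molar binding gives equal adjusted
#' response), averaged across replicates, and divided by the mean lead
#' response. The standard error propagates the replicate SEs of both means
#' through the ratio. Cells for the lead's own residue are identically 1
#' when identity members are present.
#'
#' @param screen A screen tibble as produced by [simulate_screen()] (or read
#'   from CSV with the same columns), containing lead rows flagged
#'   `is_lead`.
#' @param mw_adjust Apply the molecular-weight adjustment (default TRUE).
#' @return A `heat_map`: long tibble (`variant_code`, `position`, `wild`,
#'   `sub`, `fold`, `fold_se`, `n`) with the lead and alphabet attached;
#'   see [heat_map_matrix()] and [autoplot()].
#' @export
fold_change_map <- function(screen, mw_adjust = TRUE) {
  screen <- tibble::as_tibble(screen)
  need <- c("variant_code", "position", "sub", "mw_da", "is_lead", "replicate", "response")
  if (!all(need %in% names(screen))) {
    abort(sprintf("`screen` needs columns %s.", paste(need, collapse = ", ")))
  }
  lead_rows <- dplyr::filter(screen, .data$is_lead)
  if (nrow(lead_rows) == 0L) abort("Screen contains no lead rows (`is_lead`).")
  mw_lead <- lead_rows$mw_da[[1]]
  lead_mean <- mean(lead_rows$response)
  if (lead_mean <= 0) abort("Mean lead response must be positive.")
  lead_se <- if (nrow(lead_rows) > 1) sd(lead_rows$response) / sqrt(nrow(lead_rows)) else 0

  cells <- screen |>
    dplyr::filter(!.data$is_lead) |>
    dplyr::mutate(adj = if (mw_adjust) .data$response * mw_lead / .data$mw_da else .data$response) |>
    dplyr::group_by(.data$variant_code, .data$position, .data$wild, .data$sub) |>
    dplyr::summarise(
      m = mean(.data$adj),
      se_m = if (dplyr::n() > 1) sd(.data$adj) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold = .data$m / lead_mean,
      fold_se = abs(.data$fold) * sqrt((.data$se_m / .data$m)^2 + (lead_se / lead_mean)^2)
    ) |>
    dplyr::select("variant_code", "position", "wild", "sub", "fold", "fold_se", "n")
  structure(
    list(
      cells = cells,
      lead_name = lead_rows$variant_code[[1]],
      mw_adjusted = mw_adjust,
      alphabet = sort(unique(cells$sub))
    ),
    class = "heat_map"
  )
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf(
    "Fold-change heat map vs %s: %d cells over %d positions x {%s}%s\n",
    x$lead_name, nrow(x$cells), length(unique(x$cells$position)),
    paste(x$alphabet, collapse = ""),
    if (x$mw_adjusted) " (MW-adjusted)" else ""
  ))
  invisible(x)
}

#' @export
#' @method tidy heat_map
tidy.heat_map <- function(x, ...) x$cells

#' Heat map as a position-by-residue matrix
#'
#' @param x A `heat_map`.
#' @return Numeric matrix, rows = positions (labeled `"wild<position>"`),
#'   columns = substitution letters; unmeasured/identity cells are `NA`.
#' @export
heat_map_matrix <- function(x) {
  stopifnot(inherits(x, "heat_map"))
  cells <- x$cells
  positions <- sort(unique(cells$position))
  m <- matrix(NA_real_, nrow = length(positions), ncol = length(x$alphabet),
              dimnames = list(
                vapply(positions, function(p) {
                  paste0(cells$wild[match(p, cells$position)], p)
                }, character(1)),
                x$alphabet
              ))
  for (i in seq_len(nrow(cells))) {
    m[match(cells$position[i], positions), cells$sub[i]] <- cells$fold[i]
  }
  m
}

#' Select affinity-enhancing candidates from a heat map
#'
#' All cells at or above the fold-change threshold that are not flagged as
#' non-specific binders, sorted by fold-change descending (ties by position
#' then substitution letter, so the ordering is invariant to input order).
#' A secondary summary — the number of positions with any >10-fold cell —
#' is attached as attribute `n_positions_over_10`.
#'
#' @param map A [fold_change_map()] result.
#' @param fold_threshold Selection threshold (default 15; cells are kept
#'   when `fold >= fold_threshold`).
#' @param nonspecific Character vector of variant codes flagged as
#'   non-specific (excluded).
#' @return Tibble of candidates (`variant_code`, `position`, `wild`, `sub`,
#'   `fold`, `fold_se`).
#' @export
select_enhancing <- function(map, fold_threshold = 15, nonspecific = character(0)) {
  stopifnot(inherits(map, "heat_map"))
  if (fold_threshold <= 0) abort("`fold_threshold` must be positive.")
  out <- map$cells |>
    dplyr::filter(.data$fold >= fold_threshold,
                  !.data$variant_code %in% nonspecific,
                  .data$wild != .data$sub) |>
    dplyr::arrange(dplyr::desc(.data$fold), .data$position, .data$sub) |>
    dplyr::select("variant_code", "position", "wild", "sub", "fold", "fold_se")
  over10 <- map$cells |>
    dplyr::filter(.data$fold > 10, .data$wild != .data$sub) |>
    dplyr::distinct(.data$position) |>
    nrow()
  attr(out, "n_positions_over_10") <- over10
  out
}

#' Plan a variant combination from measured contributions
#'
#' Greedy per-position selection with an optional nearest-neighbour
#' adjacency rule. At each position the candidate with the largest
#' free-energy gain (most negative ddg) wins; losers are recorded with
#' reasons. When two chosen candidates at adjacent positions would both
#' introduce a bulky aromatic residue (by default W, Y, F) — substitutions
#' likely to crowd each other rather than contribute independently — the
#' position with the smaller |ddg| switches to its best alternative
#' substitution that avoids the clash, if one exists. Every decision is
#' logged in `$log`.
#'
#' @param contributions Tibble with columns `variant_code`, `position`,
#'   `wild`, `sub`, `ddg`, `ddg_se` (one row per candidate).
#' @param adjacency_rule Apply the bulky-adjacency rule (default TRUE).
#' @param bulky Residue class treated as bulky (default W, Y, F).
#' @return A `combination_plan` with `chosen` and `rejected` tibbles and a
#'   `log` of the rules applied. Re-planning a plan's own `chosen` set is
#'   idempotent.
#' @export
plan_combination <- function(contributions, adjacency_rule = TRUE,
                             bulky = c("W", "Y", "F")) {
  contributions <- tibble::as_tibble(contributions)
  need <- c("variant_code", "position", "sub", "ddg", "ddg_se")
  if (!all(need %in% names(contributions))) {
    abort(sprintf("`contributions` needs columns %s.", paste(need, collapse = ", ")))
  }
  log <- character(0)
  rejected <- tibble::tibble(variant_code = character(0), reason = character(0))
  if (nrow(contributions) == 0L) {
    return(structure(
      list(chosen = contributions, rejected = rejected,
           log = "no candidates: empty plan"),
      class = "combination_plan"
    ))
  }
  # deterministic candidate order: gain, then position, then letter
  cands <- dplyr::arrange(contributions, .data$ddg, .data$position, .data$sub)
  chosen <- cands |>
    dplyr::group_by(.data$position) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  losers <- dplyr::anti_join(cands, chosen, by = "variant_code")
  for (i in seq_len(nrow(losers))) {
    winner <- chosen$variant_code[chosen$position == losers$position[i]]
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      variant_code = losers$variant_code[i],
      reason = sprintf("position conflict with %s (smaller |ddG|)", winner)
    ))
  }

  if (adjacency_rule) {
    repeat {
      chosen <- dplyr::arrange(chosen, .data$position)
      pos <- chosen$position
      adj <- which(diff(pos) == 1L &
                     chosen$sub[-nrow(chosen)] %in% bulky &
                     chosen$sub[-1] %in% bulky)
      if (length(adj) == 0L) break
      i <- adj[[1]]
      pair <- chosen[c(i, i + 1L), ]
      weaker <- which.max(pair$ddg)  # smaller |ddg| (less negative)
      weak_row <- pair[weaker, ]
      alt <- cands |>
        dplyr::filter(.data$position == weak_row$position,
                      !.data$sub %in% bulky) |>
        dplyr::slice(1L)
      if (nrow(alt) == 1L) {
        log <- c(log, sprintf(
          "adjacency rule: %s and %s both introduce bulky residues at adjacent positions; %s (smaller |ddG|) replaced by %s",
          pair$variant_code[1], pair$variant_code[2],
          weak_row$variant_code, alt$variant_code
        ))
        rejected <- dplyr::bind_rows(rejected, tibble::tibble(
          variant_code = weak_row$variant_code,
          reason = sprintf("adjacent bulky-residue rule vs %s", pair$variant_code[-weaker])
        ))
        chosen <- chosen |>
          dplyr::filter(.data$position != weak_row$position) |>
          dplyr::bind_rows(alt)
      } else {
        log <- c(log, sprintf(
          "adjacency rule: %s and %s clash but no alternative exists at position %d; keeping both",
          pair$variant_code[1], pair$variant_code[2], weak_row$position
        ))
        break
      }
    }
  }
  # annotate rejected losers that would also have violated adjacency
  if (adjacency_rule && nrow(rejected) > 0L) {
    chosen <- dplyr::arrange(chosen, .data$position)
    for (i in seq_len(nrow(rejected))) {
      cand <- cands[match(rejected$variant_code[i], cands$variant_code), ]
      if (!cand$sub %in% bulky) next
      nb <- chosen |>
        dplyr::filter(abs(.data$position - cand$position) == 1L, .data$sub %in% bulky)
      if (nrow(nb) > 0L) {
        rejected$reason[i] <- paste0(
          rejected$reason[i],
          sprintf("; adjacent bulky-residue rule vs %s", nb$variant_code[[1]])
        )
      }
    }
  }
  structure(
    list(
      chosen = dplyr::arrange(chosen, .data$position),
      rejected = rejected,
      log = if (length(log)) log else "per-position best-gain selection; no adjacency conflicts"
    ),
    class = "combination_plan"
  )
}

#' @export
print.combination_plan <- function(x, ...) {
  cat(sprintf(
    "Combination plan: %s\n", paste(x$chosen$variant_code, collapse = "+")
  ))
  if (nrow(x$rejected)) {
    cat("Rejected:\n")
    for (i in seq_len(nrow(x$rejected))) {
      cat(sprintf("  %s — %s\n", x$rejected$variant_code[i], x$rejected$reason[i]))
    }
  }
  invisible(x)
}

#' @export
#' @method tidy combination_plan
tidy.combination_plan <- function(x, ...) x$chosen

#' Additive prediction for a planned combination
#'
#' Delegates to [combine_additive()] on the plan's chosen contributions.
#'
#' @param plan A [plan_combination()] result.
#' @param lead_dg,lead_se Lead free energy and SE, kcal/mol.
#' @param temperature Kelvin.
#' @return An [combine_additive()] prediction.
#' @export
predict_plan <- function(plan, lead_dg, lead_se = 0, temperature = 298.15) {
  stopifnot(inherits(plan, "combination_plan"))
  combine_additive(lead_dg, lead_se, plan$chosen, temperature = temperature)
}

#' Assess thermodynamic additivity: observed vs predicted
#'
#' For each multi-variant, the deviation is `observed - predicted`
#' (positive = weaker binding than predicted, i.e. sub-additive). Two slope
#' estimators of observed on predicted are always reported — ordinary least
#' squares with intercept, and regression through the origin — each with a
#' 95% confidence interval, because perfect additivity implies slope 1
#' under either. A pair is flagged when its |deviation| exceeds
#' `max(2 * combined SE, deviation_threshold)`.
#'
#' @param pairs Tibble with columns `variant_set` (label), `dg_obs`,
#'   `se_obs`, `dg_pred`, `se_pred` (kcal/mol).
#' @param deviation_threshold Absolute floor for flagging, kcal/mol
#'   (default 0: the 2-SE rule alone).
#' @return An `additivity_report` with the per-pair table (including
#'   `deviation`, `deviation_se`, `flagged`) and both slope fits.
#' @export
assess_additivity <- function(pairs, deviation_threshold = 0) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("variant_set", "dg_obs", "se_obs", "dg_pred", "se_pred")
  if (!all(need %in% names(pairs))) {
    abort(sprintf("`pairs` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(pairs) < 1L) abort("At least one observed/predicted pair is required.")
  pairs <- pairs |>
    dplyr::mutate(
      deviation = .data$dg_obs - .data$dg_pred,
      deviation_se = sqrt(.data$se_obs^2 + .data$se_pred^2),
      flagged = abs(.data$deviation) > pmax(2 * .data$deviation_se, deviation_threshold)
    )
  slope_tbl <- function(fit, term) {
    ci <- suppressMessages(confint(fit, term, level = 0.95))
    tibble::tibble(
      estimate = coef(fit)[[term]],
      std.error = summary(fit)$coefficients[term, "Std. Error"],
      conf.low = ci[[1]], conf.high = ci[[2]]
    )
  }
  slope_ols <- NULL
  slope_origin <- NULL
  if (nrow(pairs) >= 2L) {
    f1 <- lm(dg_obs ~ dg_pred, data = pairs)
    f0 <- lm(dg_obs ~ 0 + dg_pred, data = pairs)
    slope_ols <- slope_tbl(f1, "dg_pred")
    slope_origin <- slope_tbl(f0, "dg_pred")
  }
  structure(
    list(pairs = pairs, slope_ols = slope_ols, slope_origin = slope_origin,
         deviation_threshold = deviation_threshold),
    class = "additivity_report"
  )
}

#' @export
print.additivity_report <- function(x, ...) {
  cat(sprintf("Additivity assessment over %d variant sets\n", nrow(x$pairs)))
  if (!is.null(x$slope_ols)) {
    cat(sprintf("  OLS slope: %.3f +/- %.3f (95%% CI %.3f..%.3f)\n",
                x$slope_ols$estimate, x$slope_ols$std.error,
                x$slope_ols$conf.low, x$slope_ols$conf.high))
    cat(sprintf("  Through-origin slope: %.3f +/- %.3f (95%% CI %.3f..%.3f)\n",
                x$slope_origin$estimate, x$slope_origin$std.error,
                x$slope_origin$conf.low, x$slope_origin$conf.high))
  }
  fl <- x$pairs[x$pairs$flagged, ]
  if (nrow(fl)) {
    cat("  Flagged (|obs - pred| beyond threshold):\n")
    for (i in seq_len(nrow(fl))) {
      cat(sprintf("    %s: deviation %+0.2f kcal/mol\n", fl$variant_set[i], fl$deviation[i]))
    }
  } else {
    cat("  No deviations flagged.\n")
  }
  invisible(x)
}

#' @export
#' @method tidy additivity_report
tidy.additivity_report <- function(x, ...) x$pairs

#' @export
#' @method glance additivity_report
glance.additivity_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    slope_ols = x$slope_ols$estimate %||% NA_real_,
    slope_ols_se = x$slope_ols$std.error %||% NA_real_,
    slope_origin = x$slope_origin$estimate %||% NA_real_,
    slope_origin_se = x$slope_origin$std.error %||% NA_real_,
    n_flagged = sum(x$pairs$flagged)
  )
}
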