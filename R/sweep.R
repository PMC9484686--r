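#' Fractional effect of a modifier
#'
#' Modifier effects are reported relative to the maximum change possible for
#' that parameter: recombination `(0.5 - r_hat) / 0.5` (free recombination
#' down to none), dispersal and total-cost modifiers `(resident - hat) /
#' resident` (down to zero), and dominance/epistasis `|hat| / 3` capped at 1
#' (the logistic effect saturates, so 3 is treated as the full-effect scale;
#' the conventional "extreme" value 10 also maps to 1).
#'
#' @param type One of `"S"`, `"recombination"`, `"dominance"`, `"epistasis"`,
#'   `"dispersal"` (vectorised along `raw`).
#' @param raw Raw hat-parameter value(s).
#' @param resident Resident value of the same parameter (needed for
#'   `"dispersal"` and `"S"`).
#' @return Fraction(s) in \[0, 1\].
#' @export
fractional_effect <- function(type, raw, resident = NULL) {
  type <- match.arg(type, c("S", "recombination", "dominance", "epistasis",
                            "dispersal"), several.ok = FALSE)
  out <- switch(type,
    recombination = {
      if (any(raw < 0 | raw > 0.5)) stop("recombination out of [0, 0.5]", call. = FALSE)
      (0.5 - raw) / 0.5
    },
    dominance = ,
    epistasis = pmin(abs(raw) / 3, 1),
    dispersal = ,
    S = {
      if (is.null(resident)) stop("`resident` value required", call. = FALSE)
      if (any(raw < 0 | raw > resident)) {
        stop("raw value out of [0, resident]", call. = FALSE)
      }
      (resident - raw) / resident
    }
  )
  out
}

raw_from_fraction <- function(type, frac, resident) {
  switch(type,
    recombination = 0.5 * (1 - frac),
    dominance = ,
    epistasis = 3 * frac,
    dispersal = ,
    S = resident * (1 - frac)
  )
}

modifier_from_row <- function(type, raw, affected_loci = NULL) {
  if (length(affected_loci) == 1L && (is.na(affected_loci) || affected_loci == "all")) {
    affected_loci <- NULL
  }
  if (!is.null(affected_loci) && is.character(affected_loci)) {
    affected_loci <- as.integer(strsplit(affected_loci, ",")[[1L]])
  }
  switch(type,
    null = modifier_spec(),
    S = modifier_spec(S_hat = raw),
    recombination = modifier_spec(r_hat = raw),
    inversion = modifier_spec(r_hat = 0, r_m_hat = 0),
    dominance = modifier_spec(theta_hat = raw, affected_loci = affected_loci),
    epistasis = modifier_spec(phi_hat = raw),
    dispersal = modifier_spec(m_hat = raw),
    stop("unknown modifier type: ", type, call. = FALSE)
  )
}

#' Parameter sweeps over resident populations and modifiers
#'
#' Takes a tibble of cases — resident parameters plus a modifier type and raw
#' effect value per row — and, for each row, solves the resident equilibrium
#' (memoised across rows that share a resident parameterisation), runs the
#' invasion analysis, and returns one tidy row per case. This is the engine
#' behind [figure_preset()] grids.
#'
#' @param cases A data frame with columns `k`, `S`, `m`, `r`, `theta`, `phi`,
#'   `type`, `raw` and optionally `r_m` (default 0) and `affected_loci`
#'   (`"all"`, or comma-separated locus labels, for dominance modifiers).
#'   Missing resident columns fall back to the baseline `S = 0.1`,
#'   `m = 0.05`, `r = 0.5`, `theta = 0`, `phi = 0`.
#' @param seed Seed for every equilibrium initialisation.
#' @param tol,max_gen Convergence control passed to [solve_equilibrium()].
#' @param method Eigenvalue method, see [dominant_eigenvalue()].
#' @return A `mig_sweep` tibble: the case columns plus `effect_frac`,
#'   `lambda`, `selection`, `selection_max`, `load1`, `load2`, `converged`,
#'   `generations`, `polymorphic`. Rows whose resident equilibrium failed to
#'   converge carry `NA` selection and `converged = FALSE`.
#' @examples
#' \donttest{
#' run_sweep(figure_preset("fig6"))
#' }
#' @export
run_sweep <- function(cases, seed = 1, tol = 1e-8, max_gen = 5000,
                      method = c("eigen", "power")) {
  method <- match.arg(method)
  cases <- tibble::as_tibble(cases)
  defaults <- list(S = 0.1, m = 0.05, r = 0.5, r_m = 0, theta = 0, phi = 0,
                   affected_loci = "all")
  for (nm in names(defaults)) {
    if (!nm %in% names(cases)) cases[[nm]] <- defaults[[nm]]
  }
  stopifnot(all(c("k", "type", "raw") %in% names(cases)))

  rows <- purrr::pmap(cases, function(k, S, m, r, r_m, theta, phi, type, raw,
                                      affected_loci, ...) {
    eq <- solve_equilibrium(k = k, S = S, m = m, r = r, r_m = r_m,
                            theta = theta, phi = phi, tol = tol,
                            max_gen = max_gen, seed = seed)
    base <- tibble::tibble(
      k = k, S = S, m = m, r = r, r_m = r_m, theta = theta, phi = phi,
      type = type, affected_loci = as.character(affected_loci), raw = raw,
      effect_frac = if (type %in% c("null", "inversion")) 1 else {
        fractional_effect(type, raw,
                          resident = switch(type, dispersal = m, S = S, NULL))
      },
      load1 = eq$load[1L], load2 = eq$load[2L],
      converged = eq$converged, generations = eq$generations,
      polymorphic = check_polymorphic(eq)
    )
    if (!eq$converged) {
      return(dplyr::mutate(base, lambda = NA_real_, selection = NA_real_,
                           selection_max = NA_real_))
    }
    inv <- invasion_analysis(eq, modifier_from_row(type, raw, affected_loci),
                             method = method)
    dplyr::mutate(base, lambda = inv$lambda, selection = inv$selection,
                  selection_max = inv$selection_max)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("mig_sweep", class(out))
  out
}

#' Case grids behind the published-figure computations
#'
#' Returns the sweep cases for one of the five standard analyses:
#' * `fig2` — baseline (`S = 0.1`, `m = 0.05`, free recombination, additive
#'   fitness) at `k = 2` and `k = 5`; five modifier types swept from zero to
#'   full fractional effect.
#' * `fig3` — `k = 2..5`; each modifier type at its extreme value (dominance
#'   and epistasis 10, recombination and dispersal 0) and at a modest value
#'   (1.5, or half the resident rate).
#' * `fig4` — dominance modifiers only, masks `all` / locus 1 (linked) /
#'   locus 2 (unlinked), `k = 2` and `k = 5`, swept over effect.
#' * `fig5` — `k = 5`, ancestral epistasis `phi` varied 0..10, extreme
#'   modifiers of all four architecture parameters.
#' * `fig6` — `k = 3`, `S` varied over weak to strong selection, extreme
#'   modifiers (the recombination modifier is a full inversion).
#'
#' Grid resolutions are choices, not data: captions fix the endpoints, and
#' the `effect` / `phi_grid` / `S_grid` arguments override the defaults.
#'
#' @param fig_id One of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`.
#' @param effect Fractional-effect grid for swept modifiers.
#' @param phi_grid Ancestral epistasis grid (`fig5`).
#' @param S_grid Total-cost grid (`fig6`).
#' @param k Override the locus counts of the preset.
#' @return A tibble of cases for [run_sweep()].
#' @export
figure_preset <- function(fig_id = c("fig2", "fig3", "fig4", "fig5", "fig6"),
                          effect = seq(0, 1, by = 0.1),
                          phi_grid = 0:10,
                          S_grid = c(0.02, 0.05, 0.1, 0.15, 0.2),
                          k = NULL) {
  fig_id <- match.arg(fig_id)
  types4 <- c("recombination", "dominance", "epistasis", "dispersal")
  baseline <- list(S = 0.1, m = 0.05, r = 0.5, r_m = 0, theta = 0, phi = 0)
  grid <- switch(fig_id,
    fig2 = {
      g <- tidyr::expand_grid(k = if (is.null(k)) c(2L, 5L) else k,
                              type = c("S", types4), frac = effect)
      g$raw <- purrr::map2_dbl(g$type, g$frac, function(ty, fr) {
        raw_from_fraction(ty, fr, resident = switch(ty, dispersal = baseline$m,
                                                    S = baseline$S, NA))
      })
      g
    },
    fig3 = {
      g <- tidyr::expand_grid(k = if (is.null(k)) 2:5 else k, type = types4,
                              strength = c("extreme", "modest"))
      g$raw <- purrr::map2_dbl(g$type, g$strength, function(ty, st) {
        if (st == "extreme") {
          switch(ty, dominance = 10, epistasis = 10, 0)
        } else {
          switch(ty, dominance = 1.5, epistasis = 1.5,
                 recombination = 0.25, dispersal = baseline$m / 2)
        }
      })
      g
    },
    fig4 = {
      tidyr::expand_grid(k = if (is.null(k)) c(2L, 5L) else k,
                         type = "dominance",
                         affected_loci = c("all", "1", "2"),
                         frac = effect) |>
        dplyr::mutate(raw = 3 * .data$frac)
    },
    fig5 = {
      tidyr::expand_grid(k = if (is.null(k)) 5L else k, phi = phi_grid,
                         type = types4) |>
        dplyr::mutate(raw = dplyr::case_match(.data$type,
                                              "dominance" ~ 10,
                                              "epistasis" ~ 10,
                                              .default = 0))
    },
    fig6 = {
      tidyr::expand_grid(k = if (is.null(k)) 3L else k, S = S_grid,
                         type = c(types4[types4 != "recombination"],
                                  "inversion")) |>
        dplyr::mutate(raw = dplyr::case_match(.data$type,
                                              "dominance" ~ 10,
                                              "epistasis" ~ 10,
                                              .default = 0))
    }
  )
  for (nm in names(baseline)) {
    if (!nm %in% names(grid)) grid[[nm]] <- baseline[[nm]]
  }
  grid$preset <- fig_id
  grid
}

#' Plot a sweep
#'
#' Selection coefficient against the swept quantity, coloured by modifier
#' type and facetted by locus number. The x-axis is chosen automatically:
#' the fractional effect when it varies, otherwise whichever resident
#' parameter the sweep varies (`phi`, `S`, or `k`).
#'
#' @param object A `mig_sweep` from [run_sweep()].
#' @param x Optional column name to force onto the x-axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mig_sweep <- function(object, x = NULL, ...) {
  df <- dplyr::filter(object, .data$converged)
  if (is.null(x)) {
    candidates <- c("effect_frac", "phi", "S", "k")
    nvals <- vapply(candidates, function(v) dplyr::n_distinct(df[[v]]), 1L)
    x <- candidates[which.max(nvals)]
  }
  grp <- if (dplyr::n_distinct(df$affected_loci) > 1L) "affected_loci" else "type"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$selection,
                                        colour = .data[[grp]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = x, y = expression(lambda - 1),
                  colour = "modifier") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(df$k) > 1L) {
    p <- p + ggplot2::facet_wrap(~k, labeller = ggplot2::label_both,
                                 scales = "free_y")
  }
  p
}

#' Export a sweep as CSV plus a JSON metadata sidecar
#'
#' The CSV has a fixed header (one row per sweep case); the sidecar records
#' the seed, package version and timestamped run metadata so a sweep can be
#' reproduced byte-for-byte.
#'
#' @param sweep A `mig_sweep`.
#' @param csv Output CSV path.
#' @param json Optional sidecar path.
#' @return `sweep`, invisibly.
#' @export
write_sweep <- function(sweep, csv, json = NULL) {
  readr::write_csv(as.data.frame(sweep), csv)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(seed = attr(sweep, "seed"),
           n_cases = nrow(sweep),
           package_version = as.character(utils::packageVersion("migmod"))),
      json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(sweep)
}
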