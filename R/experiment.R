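#' The default eight-scenario parameter grid
#'
#' All combinations of 1 or 2 mating-trait loci, heterospecific:homospecific
#' mating ratio 0.5 or 0.75, and dominance coefficient 0.5 or 0.75; all other
#' parameters at the [sim_params()] defaults.
#'
#' @return A data frame with columns `n_mating_loci`, `pref_ratio`,
#'   `dominance` (8 rows).
#' @export
default_scenario_grid <- function() {
  expand.grid(n_mating_loci = c(1L, 2L),
              pref_ratio = c(0.5, 0.75),
              dominance = c(0.5, 0.75),
              KEEP.OUT.ATTRS = FALSE)
}

fit_centers <- function(pop) {
  fm <- fit_cline(allele_frequency_points(pop, "mating"))
  fn <- fit_cline(allele_frequency_points(pop, "neutral"))
  sm <- summarize_cline(fm)
  sn <- summarize_cline(fn)
  list(mating = sm, neutral = sn)
}

#' Run replicate simulations of one scenario
#'
#' Runs `n_replicates` independent simulations of one parameter combination,
#' with recorded replicate seeds `base_seed + replicate`, fits mating and
#' pooled-neutral clines, and stores final-generation summaries (center,
#' width, movement class, signed displacement). With `fit = "snapshots"` the
#' mating/neutral center trajectory is additionally extracted at every
#' snapshot (a center-over-time record of cline movement); the default fits
#' clines at the final generation only.
#'
#' @param params a [sim_params()] scenario (its `seed` field is ignored in
#'   favor of the derived replicate seeds).
#' @param n_replicates number of replicate simulations.
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param fit `"final"` or `"snapshots"`.
#' @return An object of class `scenario_result`: list with `scenario`,
#'   `replicates` (one row per replicate), `trajectories` (NULL unless
#'   `fit = "snapshots"`), `n_extinct`, `params`.
#' @export
run_scenario <- function(params, n_replicates, base_seed,
                         fit = c("final", "snapshots")) {
  fit <- match.arg(fit)
  rows <- vector("list", n_replicates)
  trajs <- if (fit == "snapshots") vector("list", n_replicates) else NULL
  n_extinct <- 0L
  for (r in seq_len(n_replicates)) {
    seed_r <- base_seed + r
    p <- params
    p$seed <- as.integer(seed_r)
    tr <- run_simulation(p)
    if (tr$extinct) {
      n_extinct <- n_extinct + 1L
      rows[[r]] <- data.frame(
        replicate = r, seed = seed_r, extinct = TRUE,
        center_mating = NA_real_, center_neutral = NA_real_,
        width_mating = NA_real_, width_neutral = NA_real_,
        movement_class = factor(NA, levels = c("RH", "S", "DH")),
        displacement = NA_real_, width_flagged = NA
      )
      next
    }
    s <- fit_centers(tr$final)
    rows[[r]] <- data.frame(
      replicate = r, seed = seed_r, extinct = FALSE,
      center_mating = s$mating$center, center_neutral = s$neutral$center,
      width_mating = s$mating$width, width_neutral = s$neutral$width,
      movement_class = s$mating$movement_class,
      displacement = displacement(s$mating$center, s$neutral$center),
      width_flagged = s$mating$width_flagged || s$neutral$width_flagged
    )
    if (fit == "snapshots") {
      gens <- unique(tr$snapshots$generation)
      tl <- lapply(gens, function(g) {
        snap <- tr$snapshots[tr$snapshots$generation == g, ]
        cm <- cline_center(fit_cline(allele_frequency_points(snap, "mating")))
        cn <- cline_center(fit_cline(allele_frequency_points(snap, "neutral")))
        data.frame(replicate = r, generation = g,
                   center_mating = cm, center_neutral = cn)
      })
      trajs[[r]] <- do.call(rbind, tl)
    }
  }
  if (n_extinct > 0L) {
    message(n_extinct, " extinct replicate(s) excluded from summaries")
  }
  structure(list(
    scenario = list(n_mating_loci = params$n_mating_loci,
                    pref_ratio = params$pref_ratio,
                    dominance = params$dominance),
    replicates = do.call(rbind, rows),
    trajectories = if (is.null(trajs)) NULL else do.call(rbind, trajs),
    n_extinct = n_extinct,
    params = params
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("scenario_result: %d mating loci, pref_ratio %g, dominance %g\n",
              s$n_mating_loci, s$pref_ratio, s$dominance))
  cat(sprintf("  %d replicates (%d extinct)\n", nrow(x$replicates),
              x$n_extinct))
  print(table(x$replicates$movement_class))
  invisible(x)
}

#' Run the full scenario grid
#'
#' @param grid a scenario grid (see [default_scenario_grid()]).
#' @param n_replicates replicates per scenario.
#' @param base_seed integer; scenario i uses base seed
#'   `base_seed + 10000 * (i - 1)` and replicate seeds derived from it.
#' @param ... passed to [sim_params()] (e.g. smaller
#'   `carrying_capacity_per_species` or `n_generations` for desk-scale runs).
#' @param fit passed to [run_scenario()].
#' @return A list of [run_scenario()] results, one per grid row.
#' @export
run_experiment <- function(grid = default_scenario_grid(), n_replicates = 50,
                           base_seed = 1, ..., fit = "final") {
  lapply(seq_len(nrow(grid)), function(i) {
    params <- sim_params(n_mating_loci = grid$n_mating_loci[i],
                         pref_ratio = grid$pref_ratio[i],
                         dominance = grid$dominance[i], ...)
    run_scenario(params, n_replicates,
                 base_seed = base_seed + 10000 * (i - 1), fit = fit)
  })
}

#' Summarize the scenario grid
#'
#' Movement-class (RH/S/DH) frequencies per scenario from final-generation
#' mating-cline centers; per scenario, a paired one-sided Wilcoxon signed-rank
#' test (mating vs neutral centers) restricted to the DH-classified
#' replicates (reported `NA` when fewer than 3); the pooled DH frequency; and
#' the mean and SD of |displacement| per scenario. A pooled Wilcoxon test
#' over all DH replicates across scenarios is included for scaled-down runs
#' where per-scenario DH subsets are small.
#'
#' @param results list of [run_scenario()] results.
#' @param alpha significance level used for the `significant` flag.
#' @return An object of class `grid_summary`: list with `per_scenario` (data
#'   frame), `pooled_dh_frequency`, `pooled_dh_wilcoxon_p`, `n_replicates`,
#'   `alpha`.
#' @export
summarize_grid <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1)
  per <- lapply(results, function(res) {
    rep_ok <- res$replicates[!res$replicates$extinct, ]
    n <- nrow(rep_ok)
    cls <- table(rep_ok$movement_class)
    dh <- rep_ok[rep_ok$movement_class == "DH", ]
    p <- if (nrow(dh) >= 3) {
      wilcoxon_displacement_test(dh$center_mating, dh$center_neutral)
    } else NA_real_
    data.frame(
      n_mating_loci = res$scenario$n_mating_loci,
      pref_ratio = res$scenario$pref_ratio,
      dominance = res$scenario$dominance,
      n = n, n_extinct = res$n_extinct,
      f_RH = as.numeric(cls["RH"]) / n,
      f_S = as.numeric(cls["S"]) / n,
      f_DH = as.numeric(cls["DH"]) / n,
      n_DH = nrow(dh),
      wilcoxon_p = p,
      significant = !is.na(p) & p < alpha,
      mean_abs_displacement = mean(abs(rep_ok$displacement)),
      sd_abs_displacement = stats::sd(abs(rep_ok$displacement)),
      mean_dh_displacement = if (nrow(dh)) mean(dh$displacement) else NA_real_
    )
  })
  per <- do.call(rbind, per)
  all_rep <- do.call(rbind, lapply(results, function(res) {
    res$replicates[!res$replicates$extinct, ]
  }))
  dh_all <- all_rep[all_rep$movement_class == "DH", ]
  pooled_p <- if (nrow(dh_all) >= 3) {
    wilcoxon_displacement_test(dh_all$center_mating, dh_all$center_neutral)
  } else NA_real_
  structure(list(per_scenario = per,
                 pooled_dh_frequency = sum(per$n_DH) / sum(per$n),
                 pooled_dh_wilcoxon_p = pooled_p,
                 n_replicates = sum(per$n),
                 alpha = alpha),
            class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat("Scenario-grid summary\n")
  print(x$per_scenario, digits = 3)
  cat(sprintf("pooled DH frequency: %.3f (%d replicates)\n",
              x$pooled_dh_frequency, x$n_replicates))
  cat(sprintf("pooled DH Wilcoxon p: %.4g\n", x$pooled_dh_wilcoxon_p))
  invisible(x)
}

#' Rescale simulated displacement to kilometers
#'
#' Optional post-processing: displacement in transect units divided by the
#' dispersal SD gives displacement in dispersal distances, which a
#' user-supplied km-per-dispersal-distance factor converts to kilometers.
#' The package does not choose the conversion factor.
#'
#' @param displacement displacement in transect units.
#' @param dispersal_sd dispersal SD of the generating scenario.
#' @param km_per_dispersal kilometers per dispersal distance.
#' @return Displacement in kilometers.
#' @export
displacement_km <- function(displacement, dispersal_sd, km_per_dispersal) {
  displacement / dispersal_sd * km_per_dispersal
}
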