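# End-to-end orchestration: simulate (or load) -> analyze -> report, fully
# deterministic under one seed, with a manifest of every parameter used.

breath_defaults <- function() {
  list(
    n_per_group = 10,
    group_medians = c(wt = 0.3, mut = 0.45, mut_treated = 0.45),
    ici_sdlog = 0.35,
    duration = 60,
    sampling_rate = 1000,
    noise_sd = 0.05,
    upper = 0.15,
    lower = -0.4,
    smooth_window = 25L,
    basis = "positive",
    k = 3L,
    linkage = "average",
    n_choices = 3
  )
}

ephys_defaults <- function() {
  list(
    n_cells = 6L,
    duration_psc = 30,
    sampling_rate = 5000,
    noise_sd = 2,
    epsc_rate = c(wt = 2, mut = 4, mut_treated = 2.2),
    ipsc_rate = c(wt = 4, mut = 1.5, mut_treated = 3.5),
    amp_mean = 30, amp_sd = 8,
    burst_prob = c(wt = 0.30, mut = 0.81, mut_treated = 0.17),
    burst_rate = 0.15, burst_events = 5L, burst_elevation = 80,
    burst_duration = 0.4,
    pair_correlation = c(wt = 0, mut = 0.4),
    n_pairs = 3L,
    drug_multiplier = c(wt = 0.5, mut = 1.5),
    spike_rate = 2, drug_window = c(120, 210), spike_duration = 360,
    df_gaba = c(wt = -5, mut = 15, mut_bumetanide = -35),
    df_cell_sd = 3, iv_conductance_ps = 20, iv_noise_sd = 0.2,
    iv_potentials = seq(-100, 60, by = 10), iv_openings = 20L,
    ltd_early = c(wt = 0.5218, mut = 0.80),
    ltd_late = c(wt = 0.7783, mut = 0.78),
    ltd_noise_sd = 0.03, ltd_sweeps_per_min = 2,
    qc_p0_bound = 30, qc_p15_bound = 40, qc_drift_max = 15
  )
}

resolve_config <- function(defaults, config) {
  if (length(config) == 0L) return(defaults)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort_param(sprintf("Unknown config entries: %s.", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, config)
}

#' Run the breathing-discrimination study end to end
#'
#' Simulates (or loads) a cohort, measures per-animal ICI distributions,
#' builds the Cliff's Delta matrix, clusters the animals on cosine distances
#' and tests each group's cluster composition against random classification.
#' Repeated with the same config and seed the run is numerically identical.
#'
#' @param config Named list overriding the defaults (animals per group, group
#'   ICI medians, thresholds 0.15/-0.4, 25-frame smoothing window, k = 3,
#'   average linkage, 3 random choices, ...); see the package vignette.
#' @param seed Integer seed for all randomness of the run.
#' @param input Optional path to a long-format ICI CSV (`animal`, `group`,
#'   `interval`); when given, simulation is skipped.
#' @param out_dir Optional directory; when given, writes `ici.csv`,
#'   `delta_matrix.csv`, `cluster_labels.csv`, `significance.json` and
#'   `manifest.json`.
#' @return An object of class `breath_report`: list with `ici`, `delta`
#'   (`delta_matrix`), `cluster` (`cluster_result`), `significance` (tibble),
#'   `config`, `seed`.
#' @export
run_breath_study <- function(config = list(), seed = 1L, input = NULL,
                             out_dir = NULL) {
  cfg <- resolve_config(breath_defaults(), config)
  if (!is.null(input)) {
    if (!file.exists(input)) {
      abort_data(sprintf("Input file not found: %s", input))
    }
    ici <- readr::read_csv(input, show_col_types = FALSE)
  } else {
    cohort <- sim_breath_cohort(
      n_per_group = cfg$n_per_group, group_medians = cfg$group_medians,
      ici_sdlog = cfg$ici_sdlog, duration = cfg$duration,
      sampling_rate = cfg$sampling_rate, noise_sd = cfg$noise_sd,
      upper = cfg$upper, lower = cfg$lower,
      smooth_window = cfg$smooth_window, seed = seed
    )
    ici <- cohort_ici(cohort, basis = cfg$basis)
  }
  dm <- delta_matrix(ici)
  cl <- cluster_animals(dm, k = cfg$k, linkage = cfg$linkage)
  sig <- cluster_significance(cl, n_choices = cfg$n_choices)
  report <- structure(
    list(ici = ici, delta = dm, cluster = cl, significance = sig,
         config = cfg, seed = seed),
    class = "breath_report"
  )
  if (!is.null(out_dir)) write_breath_report(report, out_dir)
  report
}

#' @export
print.breath_report <- function(x, ...) {
  cat(sprintf("<breath_report> %d animals, %d ICIs; k = %d\n",
              length(x$delta$animals), nrow(x$ici), x$cluster$k))
  print(x$significance)
  invisible(x)
}

write_breath_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$ici, file.path(out_dir, "ici.csv"))
  readr::write_csv(tidy(report$delta), file.path(out_dir, "delta_matrix.csv"))
  readr::write_csv(tidy(report$cluster), file.path(out_dir, "cluster_labels.csv"))
  jsonlite::write_json(report$significance, file.path(out_dir, "significance.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest <- c(report$config, list(seed = report$seed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# One cell's spontaneous-PSC quantification: detect events and compute CD.
quantify_psc_cell <- function(rate, cfg, burst_rate = 0) {
  sim <- sim_psc_train(
    duration = cfg$duration_psc, sampling_rate = cfg$sampling_rate,
    rate = rate, amp_mean = cfg$amp_mean, amp_sd = cfg$amp_sd,
    burst_rate = burst_rate, burst_events = cfg$burst_events,
    burst_elevation = cfg$burst_elevation,
    burst_duration = cfg$burst_duration, noise_sd = cfg$noise_sd
  )
  ev <- detect_events(sim$trace, noise_sd = cfg$noise_sd, polarity = "negative")
  bursts <- detect_bursts(ev, sim$trace, elevation = 60)
  list(cd = charge_density(ev, duration = cfg$duration_psc)$cd,
       n_events = nrow(ev), n_bursts = nrow(bursts))
}

#' Run the electrophysiology study end to end
#'
#' Simulates per-genotype cohorts and quantifies every readout: isoguvacine
#' effect on spike frequency (with washout QC), sEPSC/sIPSC charge densities
#' and their ratio, population-burst incidence, paired-trace Pearson
#' correlation, DF_GABA group means from single-channel I/V fits, and
#' early/late LTD. Simulated whole-cell QC records are filtered first and
#' excluded cells never reach the downstream statistics.
#'
#' @param config Named list overriding the defaults (cohort sizes, rates,
#'   multipliers, DF_GABA group means, LTD levels, QC bounds, ...).
#' @param seed Integer seed for all randomness of the run.
#' @param out_dir Optional directory; when given, writes the report tables as
#'   CSV plus `manifest.json`.
#' @return An object of class `ephys_report`: list of tibbles `drug`, `cd`,
#'   `bursts`, `paired`, `df_gaba`, `ltd`, `qc`, plus `config` and `seed`.
#' @export
run_ephys_study <- function(config = list(), seed = 1L, out_dir = NULL) {
  cfg <- resolve_config(ephys_defaults(), config)
  if (cfg$n_cells == 0L) {
    warning("Empty cohort: returning an empty report.")
    empty <- tibble()
    report <- structure(
      list(drug = empty, cd = empty, bursts = empty, paired = empty,
           df_gaba = empty, ltd = empty, qc = empty, config = cfg, seed = seed),
      class = "ephys_report"
    )
    return(report)
  }
  with_seed(seed, {
    ## whole-cell QC: simulate monitoring records, keep only passing cells
    genos <- names(cfg$epsc_rate)
    qc_records <- purrr::map_dfr(genos, function(g) {
      tibble(
        cell = sprintf("%s_%02d", g, seq_len(cfg$n_cells)),
        genotype = g,
        age_class = "P15",
        holding_pa = rnorm(cfg$n_cells, -20, 12),
        holding_drift_pct = abs(rnorm(cfg$n_cells, 6, 5)),
        ir_drift_pct = abs(rnorm(cfg$n_cells, 6, 5))
      )
    })
    qc <- qc_filter(qc_records, p0_bound = cfg$qc_p0_bound,
                    p15_bound = cfg$qc_p15_bound, drift_max = cfg$qc_drift_max)
    kept <- qc[qc$decision == "keep", ]

    ## spontaneous PSCs: charge densities and E/I ratio per kept cell
    cd <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
      g <- kept$genotype[i]
      e <- quantify_psc_cell(cfg$epsc_rate[[g]], cfg)
      ii <- quantify_psc_cell(cfg$ipsc_rate[[g]], cfg)
      tibble(cell = kept$cell[i], genotype = g,
             epsc_cd = e$cd, ipsc_cd = ii$cd,
             ei_ratio = ei_ratio(ii$cd, e$cd))
    })

    ## population bursts: per-cell incidence with genotype-dependent probability
    bursts <- purrr::map_dfr(names(cfg$burst_prob), function(g) {
      bursty <- runif(cfg$n_cells) < cfg$burst_prob[[g]]
      n_bursts <- vapply(seq_len(cfg$n_cells), function(i) {
        res <- quantify_psc_cell(cfg$epsc_rate[[min_name(cfg$epsc_rate, g)]], cfg,
                                 burst_rate = if (bursty[i]) cfg$burst_rate else 0)
        res$n_bursts
      }, numeric(1))
      tibble(genotype = g, n_cells = cfg$n_cells,
             n_bursty = sum(n_bursts > 0),
             fraction_bursty = mean(n_bursts > 0))
    })

    ## isoguvacine drug effect on spike frequency
    drug <- purrr::map_dfr(names(cfg$drug_multiplier), function(g) {
      effects <- purrr::map_dfr(seq_len(cfg$n_cells), function(i) {
        train <- sim_spike_train(
          duration = cfg$spike_duration, baseline_rate = cfg$spike_rate,
          drug_multiplier = cfg$drug_multiplier[[g]],
          drug_window = cfg$drug_window
        )
        drug_effect(train, c(0, cfg$drug_window[1]), cfg$drug_window,
                    c(cfg$drug_window[2], cfg$spike_duration))
      })
      ok <- effects[effects$washout_ok, ]
      tibble(genotype = g, n_recordings = nrow(effects),
             n_washout_ok = nrow(ok), mean_effect = mean(ok$effect))
    })

    ## paired recordings: zero-lag Pearson per genotype
    paired <- purrr::map_dfr(names(cfg$pair_correlation), function(g) {
      rs <- vapply(seq_len(cfg$n_pairs), function(i) {
        pair <- sim_psc_pair(
          duration = cfg$duration_psc, sampling_rate = cfg$sampling_rate,
          baseline_rate = cfg$epsc_rate[[min_name(cfg$epsc_rate, g)]],
          pair_correlation = cfg$pair_correlation[[g]],
          amp_mean = cfg$amp_mean, amp_sd = cfg$amp_sd,
          noise_sd = cfg$noise_sd
        )
        paired_correlation(pair$trace_a, pair$trace_b)$r
      }, numeric(1))
      tibble(genotype = g, n_pairs = cfg$n_pairs, mean_r = mean(rs))
    })

    ## DF_GABA: single-channel I/V fits per cell, group means
    df_gaba <- purrr::map_dfr(names(cfg$df_gaba), function(g) {
      dfs <- vapply(seq_len(cfg$n_cells), function(i) {
        iv <- sim_iv_dataset(
          reversal_mv = cfg$df_gaba[[g]] + rnorm(1, 0, cfg$df_cell_sd),
          conductance_ps = cfg$iv_conductance_ps,
          potentials = cfg$iv_potentials,
          openings_per_potential = cfg$iv_openings,
          current_noise_sd = cfg$iv_noise_sd
        )
        fit_iv(iv)$df_gaba_mv
      }, numeric(1))
      tibble(genotype = g, n_cells = cfg$n_cells,
             mean_df_gaba_mv = mean(dfs),
             sem_df_gaba_mv = sd(dfs) / sqrt(length(dfs)))
    })

    ## DHPG-LTD: early/late depression per genotype
    ltd <- purrr::map_dfr(names(cfg$ltd_early), function(g) {
      series <- sim_ltd_series(
        early_level = cfg$ltd_early[[g]], late_level = cfg$ltd_late[[g]],
        noise_sd = cfg$ltd_noise_sd, sweeps_per_min = cfg$ltd_sweeps_per_min
      )
      s <- ltd_summary(series)
      tibble(genotype = g, early_pct = s$early_pct, early_sem = s$early_sem,
             late_pct = s$late_pct, late_sem = s$late_sem)
    })

    report <- structure(
      list(drug = drug, cd = cd, bursts = bursts, paired = paired,
           df_gaba = df_gaba, ltd = ltd, qc = qc, config = cfg, seed = seed),
      class = "ephys_report"
    )
    if (!is.null(out_dir)) write_ephys_report(report, out_dir)
    report
  })
}

# Fall back to the first named rate when a genotype has no dedicated entry.
min_name <- function(x, g) if (g %in% names(x)) g else names(x)[1L]

#' @export
print.ephys_report <- function(x, ...) {
  cat("<ephys_report>\n")
  for (nm in c("drug", "bursts", "paired", "df_gaba", "ltd")) {
    if (nrow(x[[nm]] %||% tibble()) > 0) {
      cat("--", nm, "--\n"); print(x[[nm]])
    }
  }
  invisible(x)
}

write_ephys_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("drug", "cd", "bursts", "paired", "df_gaba", "ltd", "qc")) {
    if (nrow(report[[nm]]) > 0) {
      readr::write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  manifest <- c(report$config, list(seed = report$seed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
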