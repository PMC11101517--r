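#' Assemble a run configuration
#'
#' Accepts a YAML file path or a list.  Recognized fields: `registry_dir`
#' (read an existing bundle) or `generator` (arguments to
#' [generator_config()]), `eligibility` / `adherence` (arguments to the
#' respective config constructors), `spline_knots`, `imputation`,
#' `outcome_kinds`, `contrasts`, `horizon`, `n_boot`, `truncation`,
#' `sensitivity` (logical), `oracle` (logical: compute the counterfactual
#' truth and a recovery panel), `n_oracle`, `output_dir`, `seed`.
#'
#' @param config list or path to a YAML file.
#' @return normalized run configuration (class `run_config`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    registry_dir = NULL, generator = list(), eligibility = list(),
    adherence = list(), spline_knots = c(6, 12, 24, 48),
    imputation = "median", outcome_kinds = c("composite", "death", "mi"),
    contrasts = c("itt", "pp"), horizon = 60L, n_boot = 0L,
    truncation = NULL, sensitivity = FALSE, oracle = FALSE,
    n_oracle = 50000L, output_dir = NULL, seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full emulation pipeline from one configuration
#'
#' simulate (optional) -> build cohort -> expand -> weight -> fit ->
#' bootstrap -> sensitivity (optional) -> report tables.  Every table is
#' written as TSV together with a manifest recording the configuration
#' hash and seed; reruns with the same configuration reproduce the
#' outputs bit for bit.
#'
#' @param config a [run_config()], list, or YAML path.
#' @return object of class `pipeline_result`: the `trial_emulation`,
#'   optional `sensitivity_grid` and oracle-recovery panel, plus the
#'   output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  seeds <- derive_seeds(config$seed, 3L,
                        c("generator", "bootstrap", "oracle"))

  if (!is.null(config$registry_dir)) {
    stage_log("simulate", "reading registry from ", config$registry_dir)
    bundle <- read_registry(config$registry_dir)
    gen_cfg <- NULL
  } else {
    gen_args <- config$generator
    if (is.null(gen_args$seed)) gen_args$seed <- seeds[["generator"]]
    gen_cfg <- do.call(generator_config, gen_args)
    bundle <- generate_registry(gen_cfg)
    stage_log("simulate", nrow(bundle$persons), " persons generated")
  }

  eligibility <- do.call(eligibility_config, config$eligibility)
  adherence <- do.call(adherence_config, config$adherence)
  spline <- spline_spec(config$spline_knots)

  emu <- emulate_trial(bundle, eligibility, adherence, spline,
                       imputation = config$imputation,
                       outcome_kinds = config$outcome_kinds,
                       contrasts = config$contrasts,
                       n_boot = config$n_boot,
                       seed = seeds[["bootstrap"]],
                       horizon = config$horizon,
                       truncation = config$truncation)
  stage_log("analyze", nrow(emu$subjects), " eligible subjects; ",
            "adherence ",
            paste(sprintf("%s=%.0f%%", names(emu$adherence),
                          100 * emu$adherence), collapse = ", "))

  grid <- NULL
  if (isTRUE(config$sensitivity)) {
    grid <- sensitivity_grid(bundle, eligibility, adherence, spline,
                             horizon = config$horizon,
                             seed = seeds[["bootstrap"]])
    stage_log("sensitivity", nrow(grid$table), " variants computed")
  }

  recovery <- NULL
  if (isTRUE(config$oracle) && !is.null(gen_cfg)) {
    oracle <- compute_true_effects(gen_cfg, n_oracle = config$n_oracle,
                                   seed = seeds[["oracle"]])
    recovery <- oracle_recovery_panel(emu, oracle)
    stage_log("oracle", "recovery panel computed (n_oracle = ",
              config$n_oracle, ")")
  }

  out <- list(emulation = emu, sensitivity = grid, recovery = recovery,
              bundle_meta = bundle$meta["config_hash"],
              config = config, seeds = seeds)
  class(out) <- "pipeline_result"
  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(out, config$output_dir)
    stage_log("report", "tables written to ", config$output_dir)
  }
  out
}

# estimate-vs-truth panel for generator runs with a known oracle
oracle_recovery_panel <- function(emu, oracle) {
  itt <- emu$results$itt
  if (is.null(itt)) return(NULL)
  rows <- lapply(intersect(names(itt), oracle$effects$outcome),
                 function(oc) {
    e <- itt[[oc]]
    tr <- oracle$effects[outcome == oc]
    data.table(
      outcome = oc,
      estimand = c("risk_beta_blocker", "risk_no_beta_blocker", "rd", "rr"),
      estimate = c(e$risks[["beta_blocker"]], e$risks[["no_beta_blocker"]],
                   e$rd, e$rr),
      truth = c(tr$risk_treated, tr$risk_control, tr$true_rd_5y,
                tr$true_rr_5y))
  })
  panel <- rbindlist(rows)
  panel[, abs_error := abs(estimate - truth)]
  panel
}

effects_table <- function(emu) {
  rows <- list()
  for (ctr in names(emu$results)) {
    for (oc in names(emu$results[[ctr]])) {
      e <- emu$results[[ctr]][[oc]]
      lo <- e$ci_lower %||% setNames(rep(NA_real_, 4),
                                     c("risk_beta_blocker",
                                       "risk_no_beta_blocker", "rd", "rr"))
      hi <- e$ci_upper %||% lo
      rows[[paste(ctr, oc)]] <- data.table(
        contrast = ctr, outcome = oc,
        events_beta_blocker = e$events[["beta_blocker"]],
        events_no_beta_blocker = e$events[["no_beta_blocker"]],
        risk_beta_blocker = e$risks[["beta_blocker"]],
        risk_bb_lower = lo[["risk_beta_blocker"]],
        risk_bb_upper = hi[["risk_beta_blocker"]],
        risk_no_beta_blocker = e$risks[["no_beta_blocker"]],
        risk_nb_lower = lo[["risk_no_beta_blocker"]],
        risk_nb_upper = hi[["risk_no_beta_blocker"]],
        rd = e$rd, rd_lower = lo[["rd"]], rd_upper = hi[["rd"]],
        rr = e$rr, rr_lower = lo[["rr"]], rr_upper = hi[["rr"]])
    }
  }
  rbindlist(rows)
}

hr_table <- function(emu) {
  rows <- list()
  for (ctr in names(emu$results)) {
    for (oc in names(emu$results[[ctr]])) {
      e <- emu$results[[ctr]][[oc]]
      for (nm in names(e$hr)) {
        h <- as.integer(sub("hr_", "", nm))
        rows[[paste(ctr, oc, nm)]] <- data.table(
          contrast = ctr, outcome = oc, horizon_months = h,
          hazard_ratio = e$hr[[nm]],
          hr_lower = (e$ci_lower %||% setNames(NA_real_, nm))[nm],
          hr_upper = (e$ci_upper %||% setNames(NA_real_, nm))[nm])
      }
    }
  }
  rbindlist(rows)
}

curves_table <- function(emu) {
  rows <- list()
  for (ctr in names(emu$results)) {
    for (oc in names(emu$results[[ctr]])) {
      cv <- attr(emu$results[[ctr]][[oc]], "curves")
      if (is.null(cv)) next
      rows[[paste(ctr, oc)]] <- cbind(
        data.table(contrast = ctr, outcome = oc), as.data.table(cv))
    }
  }
  rbindlist(rows)
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emu <- result$emulation
  wr <- function(x, nm) if (!is.null(x) && nrow(x))
    fwrite(x, file.path(dir, nm), sep = "\t")
  wr(emu$flowchart, "flowchart.tsv")
  wr(emu$balance, "balance.tsv")
  wr(effects_table(emu), "effects.tsv")
  wr(hr_table(emu), "hazard_ratios.tsv")
  wr(curves_table(emu), "risk_curves.tsv")
  if (!is.null(result$sensitivity))
    wr(result$sensitivity$table, "sensitivity.tsv")
  if (!is.null(result$recovery))
    wr(result$recovery, "oracle_recovery.tsv")
  cfg_hashable <- result$config
  cfg_hashable$output_dir <- NULL  # hash the scientific config only
  manifest <- list(
    config_hash = config_hash(cfg_hashable),
    registry_hash = result$bundle_meta$config_hash,
    seed = result$config$seed,
    substream_seeds = as.list(result$seeds),
    n_eligible = nrow(emu$subjects),
    adherence = as.list(emu$adherence),
    tables = list(
      flowchart = nrow(emu$flowchart), balance = nrow(emu$balance)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Render a human-readable report from pipeline outputs
#'
#' Prints the selection flowchart, balance table, effect tables, hazard
#' ratios, and (when present) the sensitivity grid and oracle-recovery
#' panel.  Missing artifacts are noted rather than failing.
#'
#' @param x a `pipeline_result` or a directory written by
#'   [run_pipeline()].
#' @return invisibly, the lines printed.
#' @export
render_report <- function(x) {
  out <- character()
  say <- function(...) out <<- c(out, paste0(...))
  if (is.character(x)) {
    rd <- function(nm) {
      f <- file.path(x, nm)
      if (file.exists(f)) fread(f, sep = "\t") else NULL
    }
    parts <- list(flowchart = rd("flowchart.tsv"),
                  balance = rd("balance.tsv"),
                  effects = rd("effects.tsv"),
                  hr = rd("hazard_ratios.tsv"),
                  sensitivity = rd("sensitivity.tsv"),
                  recovery = rd("oracle_recovery.tsv"))
  } else {
    emu <- x$emulation
    parts <- list(flowchart = emu$flowchart, balance = emu$balance,
                  effects = effects_table(emu), hr = hr_table(emu),
                  sensitivity = if (!is.null(x$sensitivity))
                    x$sensitivity$table,
                  recovery = x$recovery)
  }
  titles <- c(flowchart = "Cohort selection",
              balance = "Covariate balance (SMD before/after IP weighting)",
              effects = "Estimated 5-year risks, risk differences and ratios",
              hr = "Average hazard ratios by horizon",
              sensitivity = "Sensitivity analyses",
              recovery = "Estimate vs simulated truth")
  for (nm in names(titles)) {
    say("== ", titles[[nm]], " ==")
    if (is.null(parts[[nm]])) {
      say("  (artifact not available)")
    } else {
      say(paste(utils::capture.output(print(parts[[nm]], digits = 3)),
                collapse = "\n"))
    }
    say("")
  }
  cat(out, sep = "\n")
  invisible(out)
}

#' Risk-curve figure with pointwise confidence bands
#'
#' Builds a ggplot of the arm-specific cumulative-risk curves; bands are
#' drawn when the curve table carries `risk_lower`/`risk_upper` columns.
#' Requires ggplot2.
#'
#' @param curves a `risk_curve` table (optionally with CI columns).
#' @return a ggplot object.
#' @export
plot_risk_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = t, y = risk, colour = arm)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "months since baseline", y = "cumulative risk") +
    ggplot2::theme_minimal()
  if (all(c("risk_lower", "risk_upper") %in% names(curves)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = risk_lower, ymax = risk_upper, fill = arm),
      alpha = 0.2, colour = NA)
  p
}
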