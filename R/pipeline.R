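#' Analysis configuration
#'
#' Validates and freezes every setting of a full bidirectional analysis
#' before any computation runs. The resolved configuration is echoed into
#' the output directory so a run can be reproduced from its artifacts.
#'
#' @param source Either `list(type = "synthetic", n_subjects =, gains =)`
#'   (gains named A/B/C) or `list(type = "csv", path =)`.
#' @param layout A [protocol_layout()].
#' @param truth Base [ground_truth()] for synthetic sources (per-group
#'   gains come from `source$gains`).
#' @param mode Model mode, `"regress-and-invert"` or `"direct-regression"`.
#' @param power Fractional exponent of the basis.
#' @param snr_exponent Outer exponent of the signal-noise ratio.
#' @param center_summary `"mean-vy"` or `"centroid-norm"`.
#' @param k_range Inclusive integer range of the standard probe signal.
#' @param out_dir Output directory, or `NULL` for no artifacts.
#' @param seed Master seed for synthetic sources.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(source = list(type = "synthetic", n_subjects = 40,
                                          gains = c(A = 1.5, B = 3.0, C = 1.0)),
                            layout = protocol_layout(),
                            truth = ground_truth(),
                            mode = c("regress-and-invert", "direct-regression"),
                            power = 0.3,
                            snr_exponent = 1 / 2,
                            center_summary = c("centroid-norm", "mean-vy"),
                            k_range = c(1L, 2400L),
                            out_dir = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  center_summary <- match.arg(center_summary)
  if (is.null(source$type) || !source$type %in% c("synthetic", "csv"))
    stop_config("source$type must be 'synthetic' or 'csv'")
  if (source$type == "synthetic") {
    if (is.null(source$n_subjects) || source$n_subjects < 1)
      stop_config("synthetic source needs n_subjects >= 1")
    if (is.null(source$gains) || !all(c("A", "B", "C") %in% names(source$gains)))
      stop_config("synthetic source needs gains named A, B, C")
  } else if (is.null(source$path)) {
    stop_config("csv source needs a path")
  }
  stopifnot(inherits(layout, "protocol_layout"), inherits(truth, "ground_truth"))
  if (length(k_range) != 2L || k_range[1] > k_range[2])
    stop_config("k_range must be two integers, start <= end")
  if (power <= 0) stop_config("power must be positive")
  structure(
    list(source = source, layout = layout, truth = truth, mode = mode,
         power = power, snr_exponent = snr_exponent,
         center_summary = center_summary,
         k_range = as.integer(k_range), out_dir = out_dir,
         seed = as.integer(seed)),
    class = "analysis_config")
}

#' Run one mapping direction for every group
#'
#' For each group dataset: build the lagged regression rows and fit the
#' mapping model, map the measured input to the estimated contralateral
#' series, compute the error series and signal-noise ratio, map the
#' standard probe signal through the same model (the probe's lag at the
#' first frame is the signal evaluated one step before `k_range[1]`), and
#' assemble the 2-D characteristic cloud. A failure in one group is
#' captured with its context and halts that group only.
#'
#' @param datasets Named list of [group_dataset()]s, one per group, all in
#'   the same direction.
#' @param config An [analysis_config()].
#' @return An object of class `flux_direction_report`: lists `models`,
#'   `evaluations`, `clouds` keyed by group, `centers` and `snrs` (named
#'   numeric), `direction`, and `failed` (named character of error
#'   messages, empty if all groups succeeded).
#' @export
run_direction <- function(datasets, config = analysis_config()) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  dirs <- unique(vapply(datasets, `[[`, "", "direction"))
  if (length(dirs) != 1L)
    stop_structural("all datasets of one report must share a direction")
  sig <- standard_signal(config$k_range[1], config$k_range[2])
  sig_lag <- standard_signal(config$k_range[1] - 1L, config$k_range[1] - 1L)$values
  models <- list(); evals <- list(); clouds <- list()
  failed <- character(0)
  for (g in names(datasets)) {
    res <- tryCatch({
      model <- fluxmap(datasets[[g]], mode = config$mode, power = config$power)
      ev <- evaluate_model(model, datasets[[g]], snr_exponent = config$snr_exponent)
      f2 <- map_series(model, sig$values, lag_seed = sig_lag)
      cloud <- characteristic_cloud(as.numeric(f2),
                                    snr = if (ev$perfect_fit) 0 else ev$snr,
                                    errors = if (ev$perfect_fit) rep(0, length(f2))
                                             else ev$errors,
                                    summary = config$center_summary)
      list(model = model, ev = ev, cloud = cloud)
    }, fluxmap_error = function(e) e)
    if (inherits(res, "condition")) {
      failed[g] <- sprintf("group %s, direction %s: %s", g, dirs, conditionMessage(res))
      next
    }
    models[[g]] <- res$model; evals[[g]] <- res$ev; clouds[[g]] <- res$cloud
  }
  structure(
    list(models = models, evaluations = evals, clouds = clouds,
         centers = vapply(clouds, `[[`, 0, "center_scalar"),
         snrs = vapply(evals, function(e) if (e$perfect_fit) NA_real_ else e$snr, 0),
         direction = dirs, failed = failed),
    class = "flux_direction_report")
}

#' @export
print.flux_direction_report <- function(x, ...) {
  cat(sprintf("Direction report %s: %d group(s)\n", x$direction, length(x$models)))
  for (g in names(x$models))
    cat(sprintf("  %s: center %.4f, sn %.4f\n", g, x$centers[[g]], x$snrs[[g]]))
  if (length(x$failed)) cat("  failed:", paste(x$failed, collapse = "; "), "\n")
  invisible(x)
}

#' Rank scalar centers and compute amplification ratios
#'
#' Orders groups by decreasing scalar distribution center and reports each
#' non-control group's center as a multiple of the control center (the
#' amplification). Exact ties are flagged and yield amplification 1 when
#' they involve the control group.
#'
#' @param centers Named numeric vector of scalar centers (must include
#'   `"C"` for amplification ratios).
#' @return List with `ranking` (group labels, decreasing), `tied` (logical),
#'   and `amplification` (named numeric, groups other than C).
#' @export
rank_centers <- function(centers) {
  ord <- names(sort(centers, decreasing = TRUE))
  tied <- anyDuplicated(unname(centers)) > 0
  amp <- if ("C" %in% names(centers)) {
    others <- setdiff(names(centers), "C")
    stats::setNames(centers[others] / centers[["C"]], others)
  } else NULL
  list(ranking = ord, tied = tied, amplification = amp)
}

#' Compare the two directions' group summaries
#'
#' Tabulates per-direction rankings of the scalar distribution centers,
#' amplification ratios relative to the control group, and whether the
#' ranking is invariant to the input/output designation.
#'
#' @param report_lr,report_rl [run_direction()] reports for the two mapping
#'   directions.
#' @return An object of class `flux_comparison`: list with `table` (one row
#'   per group and direction), `ranking` (per direction), `amplification`
#'   (per direction), `tied` and `direction_invariant`.
#' @export
compare_groups <- function(report_lr, report_rl) {
  stopifnot(inherits(report_lr, "flux_direction_report"),
            inherits(report_rl, "flux_direction_report"))
  g1 <- names(report_lr$models); g2 <- names(report_rl$models)
  if (!identical(sort(g1), sort(g2)))
    stop_structural(sprintf("group mismatch between directions: {%s} vs {%s}",
                            paste(g1, collapse = ","), paste(g2, collapse = ",")))
  mk <- function(rep) {
    data.frame(direction = rep$direction, group = names(rep$models),
               center_x = vapply(rep$clouds, function(cl) unname(cl$center["x"]), 0),
               center_y = vapply(rep$clouds, function(cl) unname(cl$center["y"]), 0),
               center_scalar = unname(rep$centers),
               snr = unname(rep$snrs),
               perfect_fit = vapply(rep$evaluations, `[[`, TRUE, "perfect_fit"),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- rbind(mk(report_lr), mk(report_rl))
  rk <- list(); amp <- list(); tied <- logical(0)
  for (rep in list(report_lr, report_rl)) {
    r <- rank_centers(rep$centers)
    rk[[rep$direction]] <- r$ranking
    amp[[rep$direction]] <- r$amplification
    tied[rep$direction] <- r$tied
  }
  structure(
    list(table = tab, ranking = rk, amplification = amp, tied = tied,
         direction_invariant = identical(rk[[1]], rk[[2]])),
    class = "flux_comparison")
}

#' @export
print.flux_comparison <- function(x, ...) {
  cat("Group comparison (scalar distribution centers)\n")
  print(x$table, row.names = FALSE)
  for (d in names(x$ranking))
    cat(sprintf("  %s ranking: %s%s\n", d, paste(x$ranking[[d]], collapse = " > "),
                if (x$tied[[d]]) " (ties present)" else ""))
  cat(sprintf("  ranking direction-invariant: %s\n", x$direction_invariant))
  invisible(x)
}

#' Run the full bidirectional analysis
#'
#' Simulates (or loads) the bilateral study, fits per-group models in both
#' mapping directions on the same data, evaluates them, probes each with
#' the standard signal, and summarises the group comparison. When
#' `config$out_dir` is set, all artifacts are written beneath it:
#' `models/*.json`, `series/*.csv`, `report/comparison.csv`,
#' `report/clouds.png`, `config_echo.yaml` and `run.log`. Reruns with an
#' identical configuration are bit-identical for synthetic sources.
#'
#' @param config An [analysis_config()].
#' @return An object of class `flux_analysis`: list with `table` (the long
#'   perfusion data frame), `lr` and `rl` direction reports, `comparison`,
#'   and `config`.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  log_lines <- character(0)
  log_add <- function(...) log_lines <<- c(log_lines, sprintf(...))
  log_add("fluxmap full bidirectional analysis")
  if (config$source$type == "synthetic") {
    truths <- study_truths(config$truth, config$source$gains)
    tab <- simulate_study(config$layout, truths, config$source$n_subjects,
                          config$seed)
    log_add("source: synthetic, %d subjects/group, master seed %d, gains A=%g B=%g C=%g",
            config$source$n_subjects, config$seed,
            config$source$gains[["A"]], config$source$gains[["B"]],
            config$source$gains[["C"]])
  } else {
    tab <- read_perfusion_csv(config$source$path)
    log_add("source: CSV %s (%d rows)", config$source$path, nrow(tab))
  }
  ds_lr <- datasets_from_table(tab, config$layout, "L->R")
  ds_rl <- datasets_from_table(tab, config$layout, "R->L")
  rep_lr <- run_direction(ds_lr, config)
  rep_rl <- run_direction(ds_rl, config)
  for (rep in list(rep_lr, rep_rl)) {
    for (g in names(rep$models)) {
      cf <- coef(rep$models[[g]])
      log_add("%s group %s: a=%.6g b=%.6g c=%.6g d=%.6g; sn=%.6g; center=%.6g",
              rep$direction, g, cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]],
              rep$snrs[[g]], rep$centers[[g]])
    }
    for (msg in rep$failed) log_add("FAILED %s", msg)
  }
  comparison <- compare_groups(rep_lr, rep_rl)
  log_add("rankings: %s | %s; direction-invariant: %s",
          paste(comparison$ranking[[1]], collapse = ">"),
          paste(comparison$ranking[[2]], collapse = ">"),
          comparison$direction_invariant)
  result <- structure(
    list(table = tab, lr = rep_lr, rl = rep_rl, comparison = comparison,
         config = config),
    class = "flux_analysis")
  if (!is.null(config$out_dir))
    write_analysis_artifacts(result, config$out_dir, log_lines)
  result
}

#' @export
print.flux_analysis <- function(x, ...) {
  cat("Bidirectional bilateral flux analysis\n")
  print(x$comparison)
  invisible(x)
}

write_analysis_artifacts <- function(result, out_dir, log_lines) {
  for (d in c("", "models", "series", "report"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  write_config_yaml(config_as_list(cfg), file.path(out_dir, "config_echo.yaml"))
  write_perfusion_csv(result$table, file.path(out_dir, "series", "perfusion.csv"))
  sig <- standard_signal(cfg$k_range[1], cfg$k_range[2])
  utils::write.csv(data.frame(k = sig$k, value = sig$values),
                   file.path(out_dir, "series", "standard_signal.csv"),
                   row.names = FALSE)
  for (rep in list(result$lr, result$rl)) {
    tag <- if (rep$direction == "L->R") "LR" else "RL"
    for (g in names(rep$models)) {
      write_model_json(rep$models[[g]],
                       file.path(out_dir, "models", sprintf("%s_%s.json", g, tag)))
      cl <- rep$clouds[[g]]
      utils::write.csv(data.frame(v_x = cl$v_x, v_y = cl$v_y),
                       file.path(out_dir, "series", sprintf("cloud_%s_%s.csv", g, tag)),
                       row.names = FALSE)
      ev <- rep$evaluations[[g]]
      utils::write.csv(data.frame(k = ev$k, estimated = ev$estimated,
                                  error = ev$errors),
                       file.path(out_dir, "series", sprintf("errors_%s_%s.csv", g, tag)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(result$comparison$table,
                   file.path(out_dir, "report", "comparison.csv"),
                   row.names = FALSE)
  plot_cloud_panels(result, file.path(out_dir, "report", "clouds.png"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

config_as_list <- function(cfg) {
  src <- cfg$source
  if (!is.null(src$gains)) src$gains <- as.list(src$gains)
  list(source = src,
       layout = list(phases = cfg$layout$phases,
                     frames_per_phase = cfg$layout$frames_per_phase,
                     excluded_phases = cfg$layout$excluded_phases),
       truth = unclass(cfg$truth),
       mode = cfg$mode, power = cfg$power, snr_exponent = cfg$snr_exponent,
       center_summary = cfg$center_summary,
       k_range = cfg$k_range, seed = cfg$seed)
}

#' Rebuild an analysis_config from its YAML echo
#'
#' @param path Path of a `config_echo.yaml` written by [run_full_analysis()].
#' @param out_dir Optional output directory for the rebuilt configuration.
#' @return An [analysis_config()].
#' @export
config_from_yaml <- function(path, out_dir = NULL) {
  doc <- read_config_yaml(path)
  src <- doc$source
  if (!is.null(src$gains)) src$gains <- unlist(src$gains)
  analysis_config(
    source = src,
    layout = protocol_layout(doc$layout$phases, doc$layout$frames_per_phase,
                             doc$layout$excluded_phases %||% character(0)),
    truth = do.call(ground_truth, doc$truth[setdiff(names(doc$truth), NULL)]),
    mode = doc$mode, power = doc$power, snr_exponent = doc$snr_exponent,
    center_summary = doc$center_summary,
    k_range = unlist(doc$k_range), out_dir = out_dir, seed = doc$seed)
}

plot_cloud_panels <- function(result, path) {
  grDevices::png(path, width = 1400, height = 700, res = 120)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  cols <- c(A = "#D55E00", B = "#0072B2", C = "#009E73")
  for (rep in list(result$lr, result$rl)) {
    xs <- unlist(lapply(rep$clouds, `[[`, "v_x"))
    ys <- unlist(lapply(rep$clouds, `[[`, "v_y"))
    graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                   xlab = "v_x = sn + d(k)", ylab = "v_y = f''(k)",
                   main = sprintf("Characteristic clouds, %s", rep$direction))
    for (g in names(rep$clouds)) {
      cl <- rep$clouds[[g]]
      graphics::points(cl$v_x, cl$v_y, pch = 16, cex = 0.3, col = cols[[g]])
      graphics::points(cl$center["x"], cl$center["y"], pch = 3, cex = 2)
    }
    graphics::legend("topright", legend = names(rep$clouds),
                     col = cols[names(rep$clouds)], pch = 16, bty = "n")
  }
  invisible(path)
}
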