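#' Simulate a full three-group bilateral study as a long table
#'
#' Generates every subject of every group with [simulate_subject()]
#' (per-subject seeds from [subject_seed()]) and returns all recorded
#' samples — including phases that will later be excluded from analysis —
#' as one long data frame, the package's canonical on-disk format.
#'
#' @param layout A [protocol_layout()].
#' @param truths Named list of per-group [ground_truth()] objects (see
#'   [study_truths()]).
#' @param n_subjects Subjects per group.
#' @param seed Master seed.
#' @return A data frame with columns `group`, `subject_id`, `side`,
#'   `phase`, `frame`, `mbf_pu`.
#' @export
simulate_study <- function(layout = protocol_layout(), truths = study_truths(),
                           n_subjects = 40, seed = 1) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop_config("n_subjects must be a positive integer")
  out <- list()
  for (g in names(truths)) {
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("%s%02d", g, s)
      pair <- simulate_subject(layout, truths[[g]], g, sid,
                               subject_seed(seed, g, s))
      for (side in c("L", "R")) {
        ser <- pair[[side]]
        out[[length(out) + 1L]] <- data.frame(
          group = ser$group, subject_id = ser$subject_id, side = ser$side,
          phase = ser$phase, frame = ser$frame, mbf_pu = ser$mbf_pu,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Read/write the long perfusion table
#'
#' The on-disk exchange format is a UTF-8 CSV with a header row and one row
#' per sample: `group, subject_id, side, phase, frame, mbf_pu`.
#'
#' @param table A data frame as produced by [simulate_study()].
#' @param path File path.
#' @return `read_perfusion_csv()` returns the validated data frame.
#' @export
write_perfusion_csv <- function(table, path) {
  validate_perfusion_table(table)
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_perfusion_csv
#' @export
read_perfusion_csv <- function(path) {
  if (!file.exists(path))
    stop_config(sprintf("perfusion CSV not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_perfusion_table(tab)
  tab
}

validate_perfusion_table <- function(tab) {
  required <- c("group", "subject_id", "side", "phase", "frame", "mbf_pu")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_structural(sprintf("perfusion table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  if (!is.numeric(tab$mbf_pu) || any(!is.finite(tab$mbf_pu)) || any(tab$mbf_pu <= 0))
    stop_positivity("perfusion table contains non-positive or non-finite mbf_pu values")
  if (!all(tab$side %in% c("L", "R")))
    stop_structural("side must be 'L' or 'R'")
  invisible(tab)
}

#' Build per-group mapping datasets from a long perfusion table
#'
#' Splits the table by group and subject, orders each side's series by the
#' layout's phase order and frame index, applies the phase exclusion, and
#' pairs the two sides into a [group_dataset()] for the requested mapping
#' direction.
#'
#' @param table Long perfusion data frame (see [simulate_study()]).
#' @param layout A [protocol_layout()].
#' @param direction `"L->R"` or `"R->L"`.
#' @return Named list of `group_dataset`s, one per group present, in
#'   group-label order.
#' @export
datasets_from_table <- function(table, layout = protocol_layout(),
                                direction = c("L->R", "R->L")) {
  direction <- match.arg(direction)
  validate_perfusion_table(table)
  groups <- sort(unique(table$group))
  res <- list()
  for (g in groups) {
    gt <- table[table$group == g, , drop = FALSE]
    subjects <- unique(gt$subject_id)
    inp <- list(); outp <- list(); subj <- list()
    for (i in seq_along(subjects)) {
      st <- gt[gt$subject_id == subjects[i], , drop = FALSE]
      sides <- lapply(c(L = "L", R = "R"), function(sd) {
        ss <- st[st$side == sd, , drop = FALSE]
        if (nrow(ss) == 0L)
          stop_structural(sprintf("subject %s has no side-%s samples", subjects[i], sd))
        ord <- order(match(ss$phase, layout$phases), ss$frame)
        ss <- ss[ord, , drop = FALSE]
        ser <- perfusion_series(g, subjects[i], sd, ss$phase, ss$frame, ss$mbf_pu)
        apply_phase_exclusion(ser, layout)
      })
      inp[[i]]  <- if (direction == "L->R") sides$L$mbf_pu else sides$R$mbf_pu
      outp[[i]] <- if (direction == "L->R") sides$R$mbf_pu else sides$L$mbf_pu
      subj[[i]] <- rep(subjects[i], length(inp[[i]]))
    }
    res[[g]] <- group_dataset(unlist(inp), unlist(outp), unlist(subj), g, direction)
  }
  res
}

#' Read or write a generator/analysis configuration document
#'
#' Configurations are plain YAML (or JSON, which YAML subsumes) documents.
#' `write_config_yaml()` echoes a fully resolved configuration;
#' `read_config_yaml()` loads one.
#'
#' @param config A named list.
#' @param path File path.
#' @return The configuration list.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(config)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}
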