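#' Read and write contribution panels as CSV
#'
#' The on-disk format is a plain CSV with exactly the panel columns
#' (`participant_id`, `matching_group_id`, `round_group_id`, `treatment`,
#' `round`, `decision`, `effective_contribution`), rounds 1-based. The
#' same reader ingests a user-supplied real dataset mapped to these
#' columns. `read_panel()` validates structure and reports the offending
#' row or group on failure: integer decisions in `[0, endowment]`,
#' consistency of `effective_contribution` with the treatment framing,
#' exactly one record per participant per round, and round groups of
#' exactly `group_size` members.
#'
#' @param path CSV file path.
#' @param panel A `contribution_panel` to write.
#' @param endowment,group_size Validation parameters of the game.
#' @param validate Set `FALSE` to skip structural checks.
#' @return `read_panel()` returns a `contribution_panel`;
#'   `write_panel()` returns `path` invisibly.
#' @export
read_panel <- function(path, endowment = 20, group_size = 4,
                       validate = TRUE) {
  cols <- c("participant_id", "matching_group_id", "round_group_id",
            "treatment", "round", "decision", "effective_contribution")
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_validation(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  df <- df[, cols]
  df$round <- as.integer(df$round)
  df$decision <- as.integer(df$decision)
  df$effective_contribution <- as.integer(df$effective_contribution)
  panel <- new_panel(df, panel_config(
    n_participants = length(unique(df$participant_id)),
    n_rounds = max(df$round),
    group_size = group_size,
    matching_group_size = max(group_size,
                              length(unique(df$participant_id)) /
                                max(1, length(unique(df$matching_group_id)))),
    endowment = endowment
  ))
  if (validate) validate_panel(panel, endowment = endowment,
                               group_size = group_size)
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(as_tibble(panel)[, c(
    "participant_id", "matching_group_id", "round_group_id", "treatment",
    "round", "decision", "effective_contribution"
  )], path)
  invisible(path)
}

#' Validate a contribution panel's structure
#'
#' @param panel A `contribution_panel`.
#' @param endowment,group_size Game parameters to validate against.
#' @return The panel, invisibly; throws a validation error naming the
#'   offending rows or groups otherwise.
#' @export
validate_panel <- function(panel, endowment = 20, group_size = 4) {
  bad <- which(!panel$treatment %in% c("provision", "maintenance"))
  if (length(bad)) {
    stop_validation(paste("unknown treatment at row", bad[1]))
  }
  bad <- which(is.na(panel$decision) | panel$decision < 0 |
                 panel$decision > endowment)
  if (length(bad)) {
    stop_validation(paste0("decision out of [0, ", endowment,
                           "] at row ", bad[1]))
  }
  expected_eff <- ifelse(panel$treatment == "provision",
                         panel$decision, endowment - panel$decision)
  bad <- which(panel$effective_contribution != expected_eff)
  if (length(bad)) {
    stop_validation(paste("effective_contribution inconsistent with",
                          "treatment at row", bad[1]))
  }
  dup <- duplicated(panel[, c("participant_id", "round")])
  if (any(dup)) {
    stop_validation(paste("duplicate participant-round record at row",
                          which(dup)[1]))
  }
  n_rec <- table(panel$participant_id)
  if (length(unique(n_rec)) != 1L) {
    stop_validation("participants have unequal numbers of records")
  }
  sizes <- panel |>
    dplyr::count(.data$round, .data$round_group_id)
  bad <- which(sizes$n != group_size)
  if (length(bad)) {
    stop_validation(paste0("round group ", sizes$round_group_id[bad[1]],
                           " in round ", sizes$round[bad[1]], " has ",
                           sizes$n[bad[1]], " members (expected ",
                           group_size, ")"))
  }
  # groups never cross matching groups
  cross <- panel |>
    dplyr::distinct(.data$round_group_id, .data$matching_group_id) |>
    dplyr::count(.data$round_group_id)
  bad <- which(cross$n != 1L)
  if (length(bad)) {
    stop_validation(paste("round group", cross$round_group_id[bad[1]],
                          "spans multiple matching groups"))
  }
  invisible(panel)
}

#' Read a panel-generator configuration from a YAML file
#'
#' Key names match the [panel_config()] arguments; unknown keys error.
#' The seed must be explicit, either in the file or via the `seed`
#' argument (which overrides the file).
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A validated `panel_config`.
#' @export
read_panel_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(panel_config)))
  if (length(unknown)) {
    stop_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$archetype_mix)) {
    vals$archetype_mix <- unlist(vals$archetype_mix)
  }
  if (!is.null(seed)) vals$seed <- seed
  if (is.null(vals$seed)) stop_config("seed must be explicit in file or call")
  do.call(panel_config, vals)
}
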