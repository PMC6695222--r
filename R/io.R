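session_log_columns <- function() {
  c("round", "period", "player_id", "partner_id", "condition",
    "regime_label", "stock_pre", "harvest", "requested", "received",
    "given", "shock", "stock_post", "alive_post")
}

#' Validate a session log
#'
#' Checks the schema and the invariants the game engine guarantees: all
#' required columns present; harvests, requests and gives non-negative; and
#' transfer symmetry (what one player gives in a period is what the partner
#' receives). Errors list every violating row, so malformed imports fail
#' loudly rather than silently skewing metrics.
#'
#' @param log A candidate session log.
#' @return The log, invisibly, if valid.
#' @export
validate_session_log <- function(log) {
  missing <- setdiff(session_log_columns(), names(log))
  if (length(missing) > 0) {
    stop("session log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_rows <- function(cond) which(!is.na(cond) & cond)
  problems <- character(0)
  for (colname in c("harvest", "requested", "given", "received")) {
    rows <- bad_rows(log[[colname]] < 0)
    if (length(rows) > 0) {
      problems <- c(problems, sprintf("%s < 0 in rows: %s", colname,
                                      paste(rows, collapse = ", ")))
    }
  }
  rows <- bad_rows(log$stock_post < 0)
  if (length(rows) > 0) {
    problems <- c(problems, sprintf("stock_post < 0 in rows: %s",
                                    paste(rows, collapse = ", ")))
  }
  # transfer symmetry: given by a player = received by the partner
  partner <- dplyr::select(log, "round", "period",
                           partner_id = "player_id", partner_given = "given")
  joined <- dplyr::left_join(log, partner,
                             by = c("round", "period", "partner_id"))
  rows <- bad_rows(abs(joined$received - joined$partner_given) > 1e-6)
  if (length(rows) > 0) {
    problems <- c(problems,
                  sprintf("received != partner's given in rows: %s",
                          paste(rows, collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("invalid session log:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(log)
}

#' Write a session log to CSV
#'
#' Writes one row per player-period with the canonical column order and a
#' comment header (lines starting `#`) recording the producing call, the
#' seed, and a hash of the configuration, so every output declares its
#' provenance.
#'
#' @param log A validated session log.
#' @param path Output path.
#' @param seed The seed the log was produced with (echoed in the header).
#' @param config The [game_config()] used (hashed into the header).
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path, seed = NA, config = NULL) {
  validate_session_log(log)
  header <- c(
    "# riskpool session log",
    sprintf("# produced: run_session/generate_experiment, seed = %s",
            as.character(seed)),
    sprintf("# config_hash = %s",
            if (is.null(config)) "none" else config_hash(config))
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(log[, session_log_columns()]), con,
                   row.names = FALSE)
  invisible(path)
}

# Small deterministic hash of a configuration (djb2 over its deparsed form).
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Column mapping for importing external tables
#'
#' Declares how an external file's columns map onto the canonical session
#' log (or metrics) fields: a named character vector `canonical = source`,
#' optional per-column unit multipliers, and an optional relabelling of
#' condition values. Built for importing the experiment's deposited
#' spreadsheet (exported to CSV), whose internal schema is not published —
#' the mapping file is the contract for whatever it contains.
#'
#' @param columns Named character vector mapping canonical field names to
#'   source column names; every canonical field must be mapped exactly once.
#' @param units Optional named numeric vector of multipliers applied to
#'   mapped numeric columns (names are canonical fields).
#' @param conditions Optional named character vector relabelling condition
#'   values (`new = old`).
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(columns, units = NULL, conditions = NULL) {
  stopifnot(is.character(columns), !is.null(names(columns)))
  if (anyDuplicated(names(columns)) || anyDuplicated(columns)) {
    stop("each field must be mapped exactly once", call. = FALSE)
  }
  structure(list(columns = columns, units = units, conditions = conditions),
            class = "column_mapping")
}

apply_mapping <- function(df, mapping) {
  missing <- setdiff(unname(mapping$columns), names(df))
  if (length(missing) > 0) {
    stop("source is missing mapped columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- df[, unname(mapping$columns), drop = FALSE]
  names(out) <- names(mapping$columns)
  for (f in names(mapping$units %||% numeric(0))) {
    out[[f]] <- out[[f]] * mapping$units[[f]]
  }
  if (!is.null(mapping$conditions) && "condition" %in% names(out)) {
    old <- unname(mapping$conditions)
    new <- names(mapping$conditions)
    idx <- match(out$condition, old)
    out$condition[!is.na(idx)] <- new[idx[!is.na(idx)]]
  }
  tibble::as_tibble(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a session log from CSV
#'
#' Reads a CSV written by [write_session_log()] (comment lines starting `#`
#' are skipped) or an external per-player-period table via a
#' [column_mapping()], validates it, and returns a tidy session log.
#'
#' @param path CSV path.
#' @param mapping Optional [column_mapping()] for external schemas.
#' @return A validated session log tibble.
#' @export
read_session_log <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (!is.null(mapping)) df <- apply_mapping(df, mapping)
  df <- tibble::as_tibble(df)
  df$alive_post <- as.logical(df$alive_post)
  validate_session_log(df)
  df[, session_log_columns()]
}

#' Write / read a player metrics table
#'
#' Plain CSV serialisation of a [player_metrics()] table, with the same
#' comment-header provenance convention as session logs. The reader accepts
#' an external per-player table (e.g. the deposited spreadsheet exported to
#' CSV) through a [column_mapping()].
#'
#' @param metrics A [player_metrics()] table.
#' @param path CSV path.
#' @param mapping Optional [column_mapping()] whose canonical names are
#'   metrics columns.
#' @return `write_metrics_table()`: `path` invisibly;
#'   `read_metrics_table()`: a metrics tibble.
#' @export
write_metrics_table <- function(metrics, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# riskpool player metrics", con)
  utils::write.csv(as.data.frame(metrics), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (!is.null(mapping)) df <- apply_mapping(df, mapping)
  df <- tibble::as_tibble(df)
  needed <- c("player_id", "condition", behavioral_variables())
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("metrics table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
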