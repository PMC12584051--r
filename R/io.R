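#' Read a billing-code table
#'
#' Reads a registry from CSV (header row, columns `code_id`, `level`,
#' `specialty`, `description`, `points`, UTF-8) or an equivalent JSON array
#' of objects. Rows with malformed point values are reported with their row
#' number; all parse errors for a file are collected into one message.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @return A `billing_registry`.
#' @seealso [write_code_table()], [validate_registry()]
#' @export
read_code_table <- function(path, format = c("csv", "json")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(format) > 1) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "json")) ext else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  raw <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
  required <- c("code_id", "level", "specialty", "description", "points")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pts <- suppressWarnings(as.numeric(raw$points))
  bad <- which(is.na(pts) | pts != trunc(pts))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: malformed points: %s", path,
      paste(sprintf("row %d ('%s' in column points)", bad, raw$points[bad]),
            collapse = "; ")), call. = FALSE)
  }
  unknown_level <- which(!raw$level %in% c("I", "II", "III"))
  if (length(unknown_level) > 0) {
    stop(sprintf(
      "%s: unknown level: %s", path,
      paste(sprintf("row %d ('%s' in column level)",
                    unknown_level, raw$level[unknown_level]),
            collapse = "; ")), call. = FALSE)
  }
  billing_registry(raw$code_id, raw$level, raw$specialty, raw$description,
                   as.integer(pts))
}

#' Write a billing-code table
#'
#' Serializes a registry to CSV or JSON such that [read_code_table()]
#' recovers it exactly (lossless round trip).
#'
#' @param registry A `billing_registry`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_code_table <- function(registry, path, format = c("csv", "json")) {
  if (length(format) > 1) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "json")) ext else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  df <- as.data.frame(registry)[, c("code_id", "level", "specialty",
                                    "description", "points")]
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# Internal: fixed two-decimal money rendering for textual report formats.
format_money <- function(x) sprintf("%.2f", x)

# Internal: strip sub-nanoeuro floating noise from report values without
# touching genuinely fractional counts.
tidy_num <- function(x) {
  if (is.numeric(x)) round_half_away(x, 9) else
    if (is.list(x)) lapply(x, tidy_num) else x
}

# Internal: flatten a result object into an ordered named list for reports.
report_fields <- function(x) {
  if (inherits(x, "cost_benefit_result")) {
    tidy_num(list(
      n = x$n,
      avoided_fn = x$avoided_fn,
      avoided_fp = x$avoided_fp,
      avoided_downstream_cost = x$avoided_downstream_cost,
      ai_spend = x$ai_spend,
      net_payer_impact = x$net_payer_impact,
      break_even_fee = x$break_even_fee,
      staff_hours_saved = x$staff_hours_saved,
      per_1000 = x$per_1000
    ))
  } else if (inherits(x, "fee_line")) {
    list(code_id = x$code_id, level = x$level, points = x$points,
         regime = x$regime, factor = x$factor, fee = x$fee,
         currency = x$currency,
         justification_note = x$justification_note)
  } else if (inherits(x, "tier_assignment")) {
    list(scores = as.list(x$scores), mean_score = x$mean_score,
         rounded_mean = x$rounded_mean, tier_points = x$tier_points,
         tier_label = x$tier_label,
         stable_under_unit_perturbation =
           as.logical(x$stable_under_unit_perturbation),
         suggested_level = x$suggested_level, rounding = x$rounding)
  } else if (is.data.frame(x)) {
    x
  } else if (is.list(x)) {
    x
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
}

#' Serialize a result as a report
#'
#' Writes any package result (tier assignments, fee lines, cost-benefit
#' results, tables) as JSON, CSV or a markdown table with deterministic
#' field ordering. JSON output round-trips: parsing it recovers the same
#' values.
#'
#' @param x Result object or data frame.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @param path Optional output file; when `NULL` the report is returned as
#'   a character string.
#' @return The serialized report (invisibly when written to `path`).
#' @export
write_report <- function(x, format = c("json", "csv", "markdown"),
                         path = NULL) {
  format <- match.arg(format)
  fields <- report_fields(x)
  out <- if (format == "json") {
    jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     null = "null")
  } else if (format == "csv") {
    df <- if (is.data.frame(fields)) fields else {
      flat <- fields[!vapply(fields, is.list, logical(1))]
      flat <- flat[!vapply(flat, is.null, logical(1))]
      as.data.frame(flat, stringsAsFactors = FALSE)
    }
    paste(utils::capture.output(
      utils::write.csv(df, row.names = FALSE)), collapse = "\n")
  } else {
    markdown_table(fields)
  }
  out <- as.character(out)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

# Internal: render a data frame or flat named list as a markdown table.
markdown_table <- function(fields) {
  if (is.data.frame(fields)) {
    df <- fields
    money_cols <- intersect(names(df), c("base_eur", "fee"))
    for (mc in money_cols) df[[mc]] <- format_money(df[[mc]])
    cells <- vapply(df, as.character, character(nrow(df)))
    if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(cells, 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    paste(c(header, sep, body), collapse = "\n")
  } else {
    flat <- fields[!vapply(fields, is.list, logical(1))]
    flat <- flat[!vapply(flat, is.null, logical(1))]
    df <- data.frame(field = names(flat),
                     value = vapply(flat, function(v) {
                       as.character(if (is.numeric(v)) format(v) else v)
                     }, character(1)),
                     stringsAsFactors = FALSE)
    markdown_table(df)
  }
}

#' Load a run configuration
#'
#' Reads a YAML configuration file and applies defaults for absent keys:
#' regime `"ebm-simplified"`, rounding `"half_up"`, AI factor cap 2.0,
#' default cohort size 1000, JSON output. Custom regimes may be defined
#' under `regimes:` (each with `euro_per_point` and optional factor policy)
#' and referenced by name; referencing an undefined regime is an error, and
#' unknown top-level keys draw a warning.
#'
#' @param path YAML file; `NULL` gives the pure defaults.
#' @return A `run_config` list with fields `regime` (resolved
#'   `point_value_regime`), `regimes`, `rounding`, `factor_cap`,
#'   `default_n`, `seed`, `output_format`.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(regime = "ebm-simplified", rounding = "half_up",
                   factor_cap = 2, default_n = 1000, seed = NULL,
                   output_format = "json")
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c(names(defaults), "regimes")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  merged <- utils::modifyList(defaults, cfg[intersect(names(cfg),
                                                      names(defaults))])
  regimes <- fee_regimes()
  for (nm in names(cfg$regimes)) {
    spec <- cfg$regimes[[nm]]
    regimes[[nm]] <- point_value_regime(
      name = nm,
      euro_per_point = spec$euro_per_point,
      factor_min = spec$factor_min %||% 1,
      factor_max = spec$factor_max %||% 1,
      typical_factor = spec$typical_factor %||% 1)
  }
  if (!merged$regime %in% names(regimes)) {
    stop(sprintf("config references undefined regime '%s'", merged$regime),
         call. = FALSE)
  }
  if (!merged$rounding %in% c("half_up", "half_even")) {
    stop("rounding must be 'half_up' or 'half_even'", call. = FALSE)
  }
  if (!merged$output_format %in% c("json", "csv", "markdown")) {
    stop("output_format must be json, csv or markdown", call. = FALSE)
  }
  structure(
    list(regime = regimes[[merged$regime]], regimes = regimes,
         rounding = merged$rounding, factor_cap = merged$factor_cap,
         default_n = assert_count(merged$default_n, "default_n"),
         seed = merged$seed, output_format = merged$output_format),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
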