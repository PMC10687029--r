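#' Construct and validate a trial table
#'
#' A trial table is the lingua franca of the package: one row per trial with
#' the participant label, condition, signed stimulus speed `s` (arbitrary
#' task units, negative = counterclockwise), binary choice (-1 =
#' counterclockwise/left, +1 = clockwise/right), binary confidence (0 = low,
#' 1 = high) and response time in seconds (`NA` allowed, flagged).
#'
#' The table carries experiment metadata: the stimulus bounds and the four
#' category boundaries `s21 < s22 = s11 < s12` that define the
#' counterclockwise category `[s21, s22]` and the clockwise category
#' `[s11, s12]` (defaults -0.3, 0, 0, 0.3).
#'
#' @param df data.frame with columns `participant_id`, `condition`, `s`,
#'   `choice`, `confidence`, `rt`.
#' @param s_bounds numeric length-2, admissible stimulus range.
#' @param category_bounds named numeric with entries `s21`, `s22`, `s11`,
#'   `s12`.
#' @param trials_per_condition optional integer, declared per-condition
#'   trial count; validated against the data when supplied.
#' @return An object of class `trial_table` (a data.frame with a `meta`
#'   attribute).
#' @export
trial_table <- function(df,
                        s_bounds = c(-0.3, 0.3),
                        category_bounds = c(s21 = -0.3, s22 = 0, s11 = 0, s12 = 0.3),
                        trials_per_condition = NULL) {
  required <- c("participant_id", "condition", "s", "choice", "confidence", "rt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$participant_id <- as.character(df$participant_id)
  df$condition <- as.character(df$condition)
  meta <- list(
    s_bounds = as.numeric(s_bounds),
    category_bounds = category_bounds,
    trials_per_condition = trials_per_condition
  )
  out <- structure(df, meta = meta, class = c("trial_table", "data.frame"))
  validate_trial_table(out)
  out
}

#' @rdname trial_table
#' @param table a `trial_table`.
#' @export
validate_trial_table <- function(table) {
  meta <- trial_meta(table)
  cb <- meta$category_bounds
  if (!(cb[["s21"]] < cb[["s22"]] && cb[["s22"]] == cb[["s11"]] && cb[["s11"]] < cb[["s12"]])) {
    stop("category bounds must satisfy s21 < s22 = s11 < s12", call. = FALSE)
  }
  check_conditions(table$condition)
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop("invalid ", what, " at row(s) ",
           paste(utils::head(which(!ok), 5L), collapse = ", "), call. = FALSE)
    }
  }
  eps <- 1e-9
  bad_row(is.finite(table$s) &
            table$s >= meta$s_bounds[1] - eps &
            table$s <= meta$s_bounds[2] + eps,
          "stimulus s (outside declared bounds)")
  bad_row(table$choice %in% c(-1, 1), "choice (must be -1 or +1)")
  bad_row(table$confidence %in% c(0, 1), "confidence (must be 0 or 1)")
  bad_row(is.na(table$rt) | table$rt > 0, "rt (must be > 0 or missing)")
  if (!is.null(meta$trials_per_condition)) {
    counts <- table(factor(table$condition, levels = unique(table$condition)))
    per_participant <- length(unique(table$participant_id))
    if (!all(counts == meta$trials_per_condition * per_participant)) {
      stop("per-condition trial counts do not match declared trials_per_condition",
           call. = FALSE)
    }
  }
  invisible(table)
}

#' Trial-table metadata
#' @param table a `trial_table`.
#' @return The `meta` attribute (stimulus bounds, category bounds, declared
#'   per-condition trial count).
#' @export
trial_meta <- function(table) {
  attr(table, "meta") %||% list(
    s_bounds = c(-0.3, 0.3),
    category_bounds = c(s21 = -0.3, s22 = 0, s11 = 0, s12 = 0.3),
    trials_per_condition = NULL
  )
}

#' @export
print.trial_table <- function(x, ...) {
  meta <- trial_meta(x)
  cat(sprintf("<trial_table> %d trials, %d participant(s), %d condition(s)\n",
              nrow(x), length(unique(x$participant_id)),
              length(unique(x$condition))))
  cat(sprintf("  s bounds [%g, %g]; categories [%g, %g] / [%g, %g]\n",
              meta$s_bounds[1], meta$s_bounds[2],
              meta$category_bounds[["s21"]], meta$category_bounds[["s22"]],
              meta$category_bounds[["s11"]], meta$category_bounds[["s12"]]))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Read a trial table from delimited text
#'
#' Files are UTF-8 delimited text (comma by default, tab accepted) with the
#' header `participant_id, condition, s, choice, confidence, rt` and
#' optional `# key: value` metadata lines written by [write_trial_table()].
#' Choices stored as `left`/`right` are mapped to -1/+1.
#'
#' @param path file path.
#' @param dialect `"auto"` (sniff the delimiter), `"csv"` or `"tsv"`.
#' @return A validated [trial_table()]; row order is preserved.
#' @export
read_trial_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) stop("no header row in ", path, call. = FALSE)
  sep <- switch(dialect,
                csv = ",",
                tsv = "\t",
                auto = if (grepl("\t", body[1])) "\t" else ",")
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if ("choice" %in% names(df) && is.character(df$choice)) {
    map <- c(left = -1, right = 1, `-1` = -1, `1` = 1)
    df$choice <- unname(map[trimws(df$choice)])
  }
  meta <- parse_meta_lines(meta_lines)
  trial_table(df,
              s_bounds = meta$s_bounds,
              category_bounds = meta$category_bounds,
              trials_per_condition = meta$trials_per_condition)
}

parse_meta_lines <- function(meta_lines) {
  defaults <- list(
    s_bounds = c(-0.3, 0.3),
    category_bounds = c(s21 = -0.3, s22 = 0, s11 = 0, s12 = 0.3),
    trials_per_condition = NULL
  )
  known <- c("s_bounds", "category_bounds", "trials_per_condition")
  for (ln in meta_lines) {
    ln <- sub("^#\\s*", "", ln)
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    if (!key %in% known) next
    val <- as.numeric(strsplit(trimws(paste(kv[-1], collapse = ":")), "\\s+")[[1]])
    if (key == "s_bounds") defaults$s_bounds <- val
    if (key == "category_bounds") {
      names(val) <- c("s21", "s22", "s11", "s12")
      defaults$category_bounds <- val
    }
    if (key == "trials_per_condition" && !any(is.na(val))) {
      defaults$trials_per_condition <- val
    }
  }
  defaults
}

#' Write a trial table to delimited text
#'
#' Writes `# key: value` metadata lines followed by a comma-delimited body.
#' `read_trial_table(write_trial_table(...))` is the identity.
#'
#' @param table a validated [trial_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table)
  meta <- trial_meta(table)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# s_bounds: %.17g %.17g", meta$s_bounds[1], meta$s_bounds[2]), con)
  writeLines(sprintf("# category_bounds: %.17g %.17g %.17g %.17g",
                     meta$category_bounds[["s21"]], meta$category_bounds[["s22"]],
                     meta$category_bounds[["s11"]], meta$category_bounds[["s12"]]), con)
  if (!is.null(meta$trials_per_condition)) {
    writeLines(sprintf("# trials_per_condition: %d",
                       as.integer(meta$trials_per_condition)), con)
  }
  writeLines("# choice coding: -1 = counterclockwise/left, +1 = clockwise/right", con)
  df <- as.data.frame(table)
  df$s <- sprintf("%.17g", df$s)
  df$rt <- ifelse(is.na(df$rt), "NA", sprintf("%.17g", df$rt))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin a response variable over stimulus speed
#'
#' Splits each condition's trials into `n_bins` equal-count bins over sorted
#' stimulus speed (stable order for ties) and reports the per-bin mean and
#' standard error (n-1 denominator) of the requested variable. With 121
#' trials and 11 bins each bin holds exactly 11 trials. Missing response
#' times are dropped before binning (per-analysis exclusion).
#'
#' @param table a [trial_table()].
#' @param variable `"choice_clockwise"` (proportion of +1 choices),
#'   `"confidence_high"` or `"rt"`.
#' @param n_bins number of bins (default 11).
#' @return A data.frame of class `binned_curve` with columns `condition`,
#'   `bin`, `center` (mean stimulus in bin), `mean`, `sem`, `n`.
#' @export
bin_curve <- function(table, variable = c("choice_clockwise", "confidence_high", "rt"),
                      n_bins = 11L) {
  variable <- match.arg(variable)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  values <- switch(variable,
                   choice_clockwise = (table$choice + 1) / 2,
                   confidence_high = table$confidence,
                   rt = table$rt)
  keep <- !is.na(values)
  s <- table$s[keep]
  values <- values[keep]
  condition <- table$condition[keep]
  out <- lapply(unique(condition), function(cond) {
    idx <- which(condition == cond)
    if (length(idx) < n_bins) {
      stop("condition ", cond, " has fewer trials (", length(idx),
           ") than bins (", n_bins, ")", call. = FALSE)
    }
    ord <- idx[order(s[idx])]  # stable sort: ties keep original order
    n <- length(ord)
    edges <- round(seq(0, n, length.out = n_bins + 1))
    assign_bin <- rep(seq_len(n_bins), times = diff(edges))
    data.frame(
      condition = cond,
      bin = seq_len(n_bins),
      center = as.numeric(tapply(s[ord], assign_bin, mean)),
      mean = as.numeric(tapply(values[ord], assign_bin, mean)),
      sem = as.numeric(tapply(values[ord], assign_bin, function(v) {
        if (length(v) < 2) return(0)
        stats::sd(v) / sqrt(length(v))
      })),
      n = as.integer(tapply(values[ord], assign_bin, length)),
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, out),
            variable = variable,
            class = c("binned_curve", "data.frame"))
}

#' Stimulus velocity from spiral frequencies
#'
#' The rotational velocity of a spiral stimulus in degrees of visual angle
#' per second is the ratio of its temporal frequency (cycles/s) to its
#' spatial frequency (cycles/degree).
#'
#' @param temporal_frequency cycles per second.
#' @param spatial_frequency cycles per degree of visual angle; must be > 0.
#' @return Velocity in degrees/s.
#' @export
spiral_velocity <- function(temporal_frequency, spatial_frequency) {
  if (any(spatial_frequency <= 0)) {
    stop("spatial_frequency must be > 0", call. = FALSE)
  }
  temporal_frequency / spatial_frequency
}
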