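#' A 5-level Likert questionnaire item
#'
#' Response counts on the standard agreement scale
#' 1 = strongly disagree ... 5 = strongly agree.
#'
#' @param category item category label (e.g. Acceptability, Accuracy,
#'   Feasibility).
#' @param statement the questionnaire statement.
#' @param counts length-5 vector of non-negative integer response counts.
#' @return An object of class `likert_item`.
#' @export
likert_item <- function(category, statement, counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 5 || any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort_ct("validation_error",
             "counts must be 5 non-negative integers (item '%s')", statement)
  }
  structure(list(category = category, statement = statement,
                 counts = as.integer(counts)),
            class = "likert_item")
}

#' Summarise one Likert item
#'
#' Computes, from the response counts: n; per-level percentages (integer,
#' rounded half-up); the mean response (reported to 1 decimal); the sample
#' standard deviation (n - 1 denominator, reported to 2 decimals) — the
#' convention that reproduces published "Mean (SD)" questionnaire tables;
#' and the agreement count (levels 4 + 5).
#'
#' @param item A [likert_item()].
#' @return list with `n`, `percent` (length 5), `mean`, `sd`,
#'   `agreement_count`, `disagreement_count`, `neutral_count`, and
#'   `mean_sd` (the formatted "m.m (s.ss)" string).
#' @examples
#' summarize_item(likert_item("Acceptability", "enjoyed", c(0, 0, 0, 3, 13)))
#' @export
summarize_item <- function(item) {
  stopifnot(inherits(item, "likert_item"))
  n <- sum(item$counts)
  if (n == 0) {
    abort_ct("validation_error", "item '%s' has no responses", item$statement)
  }
  levels <- 1:5
  total <- sum(levels * item$counts)
  mean_exact <- total / n
  var_exact <- sum(item$counts * (levels - mean_exact)^2) / max(n - 1, 1)
  if (n == 1) var_exact <- 0
  m <- round_half_up(mean_exact, 1)
  s <- round_half_up(sqrt(var_exact), 2)
  list(n = n,
       percent = as.integer(round_half_up(100 * item$counts / n)),
       mean = m,
       sd = s,
       agreement_count = item$counts[4] + item$counts[5],
       disagreement_count = item$counts[1] + item$counts[2],
       neutral_count = item$counts[3],
       mean_sd = sprintf("%.1f (%.2f)", m, s))
}

#' Summarise a questionnaire table of Likert items
#'
#' One row per item, preserving category and order, in the layout of a
#' published questionnaire summary table: n, five "count (percent%)" cells,
#' and the formatted Mean (SD).
#'
#' @param items list of [likert_item()] objects.
#' @return data.frame with columns `category`, `statement`, `n`,
#'   `level1` ... `level5` (formatted "count (pct%)"), `mean`, `sd`,
#'   `mean_sd`, `agreement_count`.
#' @export
summarize_table <- function(items) {
  if (length(items) == 0) {
    return(data.frame(category = character(), statement = character(),
                      n = integer(),
                      level1 = character(), level2 = character(),
                      level3 = character(), level4 = character(),
                      level5 = character(),
                      mean = numeric(), sd = numeric(), mean_sd = character(),
                      agreement_count = integer()))
  }
  rows <- lapply(items, function(item) {
    s <- tryCatch(summarize_item(item), ctbiopsim_error = function(e) {
      abort_ct("validation_error", "item '%s': %s", item$statement,
               conditionMessage(e))
    })
    cells <- sprintf("%d (%d%%)", item$counts, s$percent)
    data.frame(category = item$category, statement = item$statement, n = s$n,
               level1 = cells[1], level2 = cells[2], level3 = cells[3],
               level4 = cells[4], level5 = cells[5],
               mean = s$mean, sd = s$sd, mean_sd = s$mean_sd,
               agreement_count = s$agreement_count)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read Likert response counts from a delimited file
#'
#' Expects a CSV with header `category,statement,c1,c2,c3,c4,c5`.
#'
#' @param path CSV file path.
#' @return list of [likert_item()] objects.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) {
    abort_ct("io_error", "response file '%s' does not exist", path)
  }
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) abort_ct(
                   "parse_error", "failed to parse '%s': %s", path,
                   conditionMessage(e)))
  need <- c("category", "statement", "c1", "c2", "c3", "c4", "c5")
  if (!all(need %in% names(df))) {
    abort_ct("parse_error", "'%s' must have columns: %s", path,
             paste(need, collapse = ","))
  }
  lapply(seq_len(nrow(df)), function(i) {
    counts <- suppressWarnings(as.numeric(df[i, c("c1", "c2", "c3", "c4", "c5")]))
    if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
      abort_ct("parse_error",
               "row %d of '%s': counts must be non-negative integers", i, path)
    }
    likert_item(df$category[i], df$statement[i], counts)
  })
}

#' Write Likert items back to the CSV layout of [read_responses()]
#'
#' @param items list of [likert_item()] objects.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_responses <- function(items, path) {
  df <- do.call(rbind, lapply(items, function(it) {
    data.frame(category = it$category, statement = it$statement,
               c1 = it$counts[1], c2 = it$counts[2], c3 = it$counts[3],
               c4 = it$counts[4], c5 = it$counts[5])
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
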