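#' DSM-IV symptom item labels
#'
#' The 17 DSM-IV PTSD symptom items of the Davidson Trauma Scale in the fixed
#' order used for all matrix input/output: five re-experiencing items
#' (B1-B5), two avoidance items (C1, C2), four numbing items (D1, D5-D7; the
#' DSM-5 additions D2-D4 are not part of this instrument), and six arousal
#' items (E1-E6). Keeping the order fixed makes edge indices stable across
#' datasets and runs.
#'
#' @return character vector of 17 item labels.
#' @export
ptsd_items <- function() {
  c("B1", "B2", "B3", "B4", "B5",
    "C1", "C2",
    "D1", "D5", "D6", "D7",
    "E1", "E2", "E3", "E4", "E5", "E6")
}

#' Construct a symptom dataset
#'
#' A case-by-item matrix of ordinal symptom severities, each item scored on a
#' 0-4 Likert scale (0 = not at all distressing, 4 = extremely distressing),
#' with optional per-case group labels and covariates.
#'
#' @param scores numeric matrix, cases in rows, items in columns; every entry
#'   must be an integer in 0..4 with no missing values.
#' @param items item labels; defaults to `colnames(scores)`.
#' @param group optional per-case categorical label (length `nrow(scores)`).
#' @param covariates optional data frame of per-case covariates
#'   (e.g. `age`, `ces`, `sex`, `race`).
#' @return an object of class `symptom_dataset`.
#' @export
symptom_dataset <- function(scores, items = colnames(scores), group = NULL,
                            covariates = NULL) {
  scores <- as.matrix(scores)
  if (is.null(items)) stop_validation("item labels are required")
  if (anyDuplicated(items)) stop_validation("item labels must be unique")
  if (length(items) != ncol(scores))
    stop_validation("length of `items` (%d) != number of score columns (%d)",
                    length(items), ncol(scores))
  if (nrow(scores) < 1L) stop_validation("need at least one case")
  if (anyNA(scores)) stop_validation("scores contain missing values")
  bad <- which(!(scores %in% 0:4), arr.ind = TRUE)
  if (length(bad)) {
    stop_validation("score out of range 0..4 at row %d, item '%s' (value %s)",
                    bad[1, 1], items[bad[1, 2]], scores[bad[1, 1], bad[1, 2]])
  }
  storage.mode(scores) <- "integer"
  colnames(scores) <- items
  if (!is.null(group)) {
    if (length(group) != nrow(scores))
      stop_validation("`group` must have one label per case")
    group <- as.character(group)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(scores))
      stop_validation("`covariates` must have one row per case")
  }
  structure(list(scores = scores, items = items, group = group,
                 covariates = covariates),
            class = "symptom_dataset")
}

#' @export
print.symptom_dataset <- function(x, ...) {
  cat(sprintf("<symptom_dataset> %d cases x %d items\n",
              nrow(x$scores), length(x$items)))
  cat("items:", paste(x$items, collapse = " "), "\n")
  if (!is.null(x$group))
    cat("groups:", paste(names(table(x$group)), table(x$group),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of cases in a symptom dataset
#' @param data a `symptom_dataset`.
#' @return integer case count.
#' @export
n_cases <- function(data) {
  stopifnot(inherits(data, "symptom_dataset"))
  nrow(data$scores)
}

#' Load a symptom dataset from CSV
#'
#' Reads a case-per-row CSV whose columns include the 17 item labels (plus
#' optional `group`, `ces`, `age`, `sex`, `race` columns). Cases with any
#' missing item score are dropped (complete-case analysis) and counted in a
#' warning; out-of-range scores are a hard error naming the offending cell.
#'
#' @param path CSV file path.
#' @param item_columns names of the item columns; default [ptsd_items()].
#' @return a [symptom_dataset()].
#' @export
load_dataset <- function(path, item_columns = ptsd_items()) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(item_columns, names(raw))
  if (length(missing_cols))
    stop_validation("missing item column(s): %s",
                    paste(missing_cols, collapse = ", "))
  sc <- as.matrix(raw[, item_columns, drop = FALSE])
  if (!is.numeric(sc)) stop_validation("item columns must be numeric")
  ok <- !(sc %in% 0:4) & !is.na(sc)
  bad <- which(matrix(ok, nrow(sc)), arr.ind = TRUE)
  if (length(bad))
    stop_validation("score out of range 0..4 at row %d, column '%s' (value %s)",
                    bad[1, 1], item_columns[bad[1, 2]],
                    sc[bad[1, 1], bad[1, 2]])
  keep <- complete.cases(sc)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(sprintf("dropped %d case(s) with missing item scores", n_dropped),
            call. = FALSE)
  if (!any(keep)) stop_validation("no complete cases in %s", path)
  sc <- sc[keep, , drop = FALSE]
  group <- if ("group" %in% names(raw)) raw$group[keep] else NULL
  cov_cols <- intersect(c("ces", "age", "sex", "race", "dts"), names(raw))
  covariates <- if (length(cov_cols))
    raw[keep, cov_cols, drop = FALSE] else NULL
  ds <- symptom_dataset(sc, items = item_columns, group = group,
                        covariates = covariates)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Total symptom severity score
#'
#' Sum of the 17 item severities (each 0-4); totals range 0-68.
#'
#' @param case_scores numeric vector of 17 item scores.
#' @return integer total in 0..68.
#' @export
dts_total <- function(case_scores) {
  if (length(case_scores) != 17L)
    stop_validation("expected 17 item scores, got %d", length(case_scores))
  if (anyNA(case_scores) || !all(case_scores %in% 0:4))
    stop_validation("item scores must all be in 0..4")
  as.integer(sum(case_scores))
}

ces_bounds <- data.frame(
  name  = c("Light", "Light-moderate", "Moderate", "Moderate-heavy", "Heavy"),
  lower = c(0L, 9L, 17L, 25L, 33L),
  upper = c(8L, 16L, 24L, 32L, 41L),
  stringsAsFactors = FALSE
)

#' Combat-exposure category bands
#'
#' The named score bands of the Combat Exposure Scale: Light (0-8),
#' Light-moderate (9-16), Moderate (17-24), Moderate-heavy (25-32),
#' Heavy (33-41). The bands partition 0..41 with no gaps or overlaps.
#'
#' @return data frame with columns `name`, `lower`, `upper`.
#' @export
ces_categories <- function() ces_bounds

#' Combat-exposure category of a score
#'
#' @param score integer Combat Exposure Scale total in 0..41.
#' @return category name (character).
#' @export
ces_category <- function(score) {
  if (length(score) != 1L || is.na(score) || score %% 1 != 0 ||
      score < 0 || score > 41)
    stop_validation("CES score must be a single integer in 0..41")
  ces_bounds$name[score >= ces_bounds$lower & score <= ces_bounds$upper]
}

#' Low/high combat-exposure group
#'
#' Dichotomizes a Combat Exposure Scale score at a cut point; scores at or
#' above the cut are assigned to the high group, so the default cut of 25
#' aligns the group boundary with the opening of the Moderate-heavy band.
#'
#' @param score CES score in 0..41 (vectorized).
#' @param cut cut score, default 25.
#' @return character vector of `"low"` / `"high"`.
#' @export
combat_group <- function(score, cut = 25) {
  if (anyNA(score) || any(score < 0 | score > 41))
    stop_validation("CES scores must be in 0..41")
  ifelse(score >= cut, "high", "low")
}

#' Diagnostic status from DSM-IV criterion flags
#'
#' Full diagnosis requires all six criteria A-F. Subthreshold status requires
#' criteria A, E and F plus exactly two of the symptom-cluster criteria B, C
#' and D. Everything else is classified as neither.
#'
#' @param criteria_met named logical vector with elements `A`,`B`,`C`,`D`,`E`,`F`.
#' @return one of `"full"`, `"subthreshold"`, `"neither"`.
#' @export
subthreshold_status <- function(criteria_met) {
  need <- c("A", "B", "C", "D", "E", "F")
  if (!all(need %in% names(criteria_met)))
    stop_validation("`criteria_met` must contain named flags A..F")
  f <- as.logical(criteria_met[need])
  if (anyNA(f)) stop_validation("criterion flags must be TRUE/FALSE")
  bcd <- sum(f[2:4])
  if (all(f)) return("full")
  if (f[1] && f[5] && f[6] && bcd == 2L) return("subthreshold")
  "neither"
}
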