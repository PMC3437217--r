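# RAND/UCLA-style panel aggregation: mean validity/feasibility scores and
# threshold classification of candidate quality-of-care indicators.

#' Read a panel rating sheet
#'
#' One row per candidate x panelist with integer 1-9 scores on validity and
#' feasibility, plus a round label (the method runs repeated rating rounds;
#' classification conventionally uses the final round).
#'
#' @param path CSV with columns `candidate_id`, `panelist_id`, `validity`,
#'   `feasibility`, `round`.
#' @return validated data frame.
#' @export
read_rating_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("candidate_id", "panelist_id", "validity", "feasibility",
            "round")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: rating sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  .validate_scores(df$validity)
  .validate_scores(df$feasibility)
  df
}

.validate_scores <- function(x) {
  if (any(is.na(x)) || any(x != as.integer(x)) || any(x < 1) || any(x > 9)) {
    stop("validation error: scores must be integers in [1, 9]",
         call. = FALSE)
  }
  invisible(x)
}

#' Per-candidate mean validity and feasibility scores
#'
#' Arithmetic means across panelists, reported half-up to one decimal (the
#' precision at which panel results are tabulated and classified).
#'
#' @param ratings data frame as returned by [read_rating_sheet()].
#' @param round_label optional round to restrict to; default: the final
#'   (maximum) round present.
#' @return data frame with `candidate_id`, `n_panelists`, `mean_validity`,
#'   `mean_feasibility`.
#' @export
mean_scores <- function(ratings, round_label = NULL) {
  .validate_scores(ratings$validity)
  .validate_scores(ratings$feasibility)
  if (is.null(round_label)) round_label <- max(ratings$round)
  r <- ratings[ratings$round == round_label, , drop = FALSE]
  if (nrow(r) == 0) stop("no ratings in round '", round_label, "'",
                         call. = FALSE)
  agg <- aggregate(cbind(validity, feasibility) ~ candidate_id, data = r,
                   FUN = mean)
  data.frame(candidate_id = agg$candidate_id,
             n_panelists = as.vector(table(r$candidate_id)[agg$candidate_id]),
             mean_validity = round_half_up(agg$validity, 1),
             mean_feasibility = round_half_up(agg$feasibility, 1),
             stringsAsFactors = FALSE)
}

#' Classify a candidate indicator from its panel means
#'
#' Accepted iff the mean score is at or above the threshold on *both*
#' domains (the threshold is inclusive: a feasibility mean of exactly 7.0
#' accepts). Vectorised.
#'
#' @param mean_validity,mean_feasibility numeric vectors in \[1, 9\].
#' @param threshold acceptance threshold (default 7).
#' @return character vector, `"accepted"` or `"discarded"`.
#' @export
classify_candidate <- function(mean_validity, mean_feasibility,
                               threshold = 7) {
  stopifnot(all(mean_validity >= 1 & mean_validity <= 9),
            all(mean_feasibility >= 1 & mean_feasibility <= 9))
  ifelse(mean_validity >= threshold & mean_feasibility >= threshold,
         "accepted", "discarded")
}

#' Aggregate a rating sheet into panel decisions
#'
#' @param ratings data frame as returned by [read_rating_sheet()].
#' @param threshold acceptance threshold on both domain means.
#' @param round_label rating round to use; default final round.
#' @return data frame with per-candidate means (1 decimal) and `status`.
#' @export
panel_decisions <- function(ratings, threshold = 7, round_label = NULL) {
  m <- mean_scores(ratings, round_label)
  m$status <- classify_candidate(m$mean_validity, m$mean_feasibility,
                                 threshold)
  m
}

#' The candidate indicator catalog with panel means
#'
#' Twenty-three candidate quality-of-care indicators for T2DM primary care
#' with their panel mean validity/feasibility scores, acceptance status, and
#' whether the indicator is programmable from structured EHR fields. The 14
#' entries that are both accepted and programmable are `active` and are the
#' ones the engine evaluates (ids P1-P9 for process, O1-O5 for outcomes).
#'
#' @param path catalog CSV; defaults to the copy shipped with the package.
#' @return data frame with columns `id`, `row`, `title`, `family`,
#'   `validity`, `feasibility`, `status`, `programmable`, `active`.
#' @export
indicator_catalog <- function(path = system.file("extdata",
                                                 "indicator_catalog.csv",
                                                 package = "diabqc")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$programmable <- as.logical(df$programmable)
  df$active <- df$status == "accepted" & df$programmable
  df
}
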