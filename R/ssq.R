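# Simulator Sickness Questionnaire (SSQ) scoring.
#
# 16 symptom items rated 0-3 feed three non-mutually-exclusive factors --
# nausea (N), oculomotor (O), disorientation (D) -- whose raw sums are
# weighted into the standard subscale and total scores.

SSQ_WEIGHTS <- c(n = 9.54, o = 7.58, d = 13.92, total = 3.74)

.ssq_item_table <- function() {
  items <- c("general_discomfort", "fatigue", "headache", "eyestrain",
             "difficulty_focusing", "increased_salivation", "sweating",
             "nausea", "difficulty_concentrating", "fullness_of_head",
             "blurred_vision", "dizziness_eyes_open", "dizziness_eyes_closed",
             "vertigo", "stomach_awareness", "burping")
  n_items <- c("general_discomfort", "increased_salivation", "sweating",
               "nausea", "difficulty_concentrating", "stomach_awareness",
               "burping")
  o_items <- c("general_discomfort", "fatigue", "headache", "eyestrain",
               "difficulty_focusing", "difficulty_concentrating",
               "blurred_vision")
  d_items <- c("difficulty_focusing", "nausea", "fullness_of_head",
               "blurred_vision", "dizziness_eyes_open",
               "dizziness_eyes_closed", "vertigo")
  data.frame(item = items,
             nausea = items %in% n_items,
             oculomotor = items %in% o_items,
             disorientation = items %in% d_items,
             stringsAsFactors = FALSE)
}

#' SSQ item-factor membership matrix
#'
#' The 16 symptom items and their (overlapping) membership in the nausea,
#' oculomotor and disorientation factors; exposed read-only for audit.
#'
#' @return A data frame with columns `item`, `nausea`, `oculomotor`,
#'   `disorientation` (7 `TRUE` per factor).
#' @export
ssq_items <- function() .ssq_item_table()

#' Construct and validate an SSQ response
#'
#' @param ratings Named numeric vector (or 1-row data frame) of the 16
#'   item ratings, each in `{0, 1, 2, 3}`; names must match
#'   `ssq_items()$item`.
#' @return An object of class `ssq_response`.
#' @export
ssq_response <- function(ratings) {
  if (is.data.frame(ratings)) {
    stopifnot(nrow(ratings) == 1L)
    ratings <- unlist(ratings[1, , drop = TRUE])
  }
  items <- .ssq_item_table()$item
  if (is.null(names(ratings))) stop_vims("SSQ ratings must be named by item")
  missing <- setdiff(items, names(ratings))
  if (length(missing)) {
    stop_vims("missing SSQ item(s): ", paste(missing, collapse = ", "))
  }
  ratings <- ratings[items]
  if (!all(ratings %in% 0:3)) {
    bad <- names(ratings)[!(ratings %in% 0:3)]
    stop_vims("SSQ ratings must be in {0,1,2,3}; out of range: ",
              paste(bad, collapse = ", "))
  }
  structure(as.numeric(ratings), names = items, class = "ssq_response")
}

#' Score an SSQ response
#'
#' Raw factor sums N, O, D are taken over the (overlapping) item-factor
#' memberships; weighted scores are `N x 9.54`, `O x 7.58`, `D x 13.92`
#' and total `(N + O + D) x 3.74` (the Kennedy convention).
#'
#' @param resp An [ssq_response()] (or anything it accepts).
#' @return An `ssq_scores` list: `n_raw`, `o_raw`, `d_raw`, `n_score`,
#'   `o_score`, `d_score`, `total`.
#' @examples
#' r <- setNames(rep(0, 16), ssq_items()$item)
#' r["general_discomfort"] <- 1   # member of both N and O
#' score_ssq(r)$total             # 2 * 3.74
#' @export
score_ssq <- function(resp) {
  if (!inherits(resp, "ssq_response")) resp <- ssq_response(resp)
  tab <- .ssq_item_table()
  n_raw <- sum(resp[tab$nausea])
  o_raw <- sum(resp[tab$oculomotor])
  d_raw <- sum(resp[tab$disorientation])
  structure(
    list(n_raw = n_raw, o_raw = o_raw, d_raw = d_raw,
         n_score = SSQ_WEIGHTS[["n"]] * n_raw,
         o_score = SSQ_WEIGHTS[["o"]] * o_raw,
         d_score = SSQ_WEIGHTS[["d"]] * d_raw,
         total = SSQ_WEIGHTS[["total"]] * (n_raw + o_raw + d_raw)),
    class = "ssq_scores"
  )
}

#' @export
print.ssq_scores <- function(x, ...) {
  cat(sprintf("<ssq_scores> N %.2f | O %.2f | D %.2f | total %.2f\n",
              x$n_score, x$o_score, x$d_score, x$total))
  invisible(x)
}
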