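#' Enrolled subjects of the OHD validation cohort
#'
#' Bookkeeping helpers for the validation cohort: 24 mice (12 female,
#' 12 male), each scheduled for two testing sessions two weeks apart.
#'
#' @return A data.frame with one row per subject x session: `subject`,
#'   `sex`, `session`.
#' @export
ohd_study_cohort <- function() {
  subj <- sprintf("%s%02d", rep(c("F", "M"), each = 12L), rep(1:12, 2L))
  sex <- rep(c("female", "male"), each = 12L)
  do.call(rbind, lapply(1:2, function(s)
    data.frame(subject = subj, sex = sex, session = s,
               stringsAsFactors = FALSE)))
}

#' Stated exclusions for the validation cohort
#'
#' Two male subjects lost from the second session: one killed after
#' home-cage aggression before session 2, one tested but with the session
#' video lost to a technical fault. No first-session data were excluded.
#'
#' @return A data.frame with `subject`, `session`, `reason`.
#' @export
ohd_study_exclusions <- function() {
  data.frame(subject = c("M11", "M12"), session = c(2L, 2L),
             reason = c("killed after home-cage aggression",
                        "video not saved"),
             stringsAsFactors = FALSE)
}

#' Remove excluded subject-sessions from a cohort table
#'
#' @param subjects Data.frame with `subject` and `session` columns.
#' @param exclusions Data.frame with `subject` and `session` columns naming
#'   the subject-sessions to drop.
#' @return `subjects` without the excluded rows.
#' @export
exclude_subjects <- function(subjects, exclusions) {
  stopifnot(all(c("subject", "session") %in% names(subjects)),
            all(c("subject", "session") %in% names(exclusions)))
  key <- function(df) paste(df$subject, df$session, sep = "\r")
  subjects[!key(subjects) %in% key(exclusions), , drop = FALSE]
}

#' Analyzable subjects per session
#'
#' @inheritParams exclude_subjects
#' @return Data.frame with `session` and `n_analyzable`.
#' @export
#' @examples
#' cohort_counts(ohd_study_cohort(), ohd_study_exclusions())
cohort_counts <- function(subjects = ohd_study_cohort(),
                          exclusions = ohd_study_exclusions()) {
  kept <- exclude_subjects(subjects, exclusions)
  agg <- stats::aggregate(list(n_analyzable = kept$subject),
                          by = list(session = kept$session),
                          FUN = function(x) length(unique(x)))
  agg[order(agg$session), , drop = FALSE]
}
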