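#' Per-subject habituation differences
#'
#' For each stimulus and subject, the change in investigation duration from
#' the first to the final (third) presentation:
#' `duration(final) - duration(first)`. Negative values indicate
#' habituation. Subjects missing either presentation for a stimulus are
#' skipped with a warning.
#'
#' @param scores Trial-score data.frame from [score_trials()] (columns
#'   `subject`, `stimulus`, `presentation`, `duration_s`).
#' @param first,final Presentation numbers compared (defaults 1 and 3).
#' @return Data.frame with `stimulus`, `subject`, `diff_s`.
#' @export
habituation_diffs <- function(scores, first = 1L, final = 3L) {
  stopifnot(all(c("subject", "stimulus", "presentation", "duration_s")
                %in% names(scores)))
  out <- list()
  for (stim in unique(scores$stimulus)) {
    ss <- scores[scores$stimulus == stim, , drop = FALSE]
    for (subj in unique(ss$subject)) {
      d1 <- ss$duration_s[ss$subject == subj & ss$presentation == first]
      d3 <- ss$duration_s[ss$subject == subj & ss$presentation == final]
      if (length(d1) != 1L || length(d3) != 1L) {
        warning(sprintf("subject %s missing presentation %d or %d for %s; skipped",
                        subj, first, final, stim), call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(stimulus = stim, subject = subj,
                                            diff_s = d3 - d1,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(stimulus = character(0), subject = character(0),
                      diff_s = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-subject dishabituation differences
#'
#' For each adjacent stimulus pair in presentation order, the change from
#' the final presentation of the earlier stimulus to the first presentation
#' of the next: `duration(next, first) - duration(previous, final)`.
#' Positive values indicate dishabituation.
#'
#' @inheritParams habituation_diffs
#' @param stimulus_order Stimulus labels in presentation order; defaults to
#'   their order of appearance in `scores`.
#' @return Data.frame with `from`, `to`, `pair`, `subject`, `diff_s`.
#' @export
dishabituation_diffs <- function(scores, stimulus_order = NULL,
                                 first = 1L, final = 3L) {
  stopifnot(all(c("subject", "stimulus", "presentation", "duration_s")
                %in% names(scores)))
  if (is.null(stimulus_order)) stimulus_order <- unique(scores$stimulus)
  out <- list()
  for (k in seq_len(length(stimulus_order) - 1L)) {
    prev <- stimulus_order[k]; nxt <- stimulus_order[k + 1L]
    for (subj in unique(scores$subject)) {
      d_prev <- scores$duration_s[scores$subject == subj &
                                    scores$stimulus == prev &
                                    scores$presentation == final]
      d_next <- scores$duration_s[scores$subject == subj &
                                    scores$stimulus == nxt &
                                    scores$presentation == first]
      if (length(d_prev) != 1L || length(d_next) != 1L) {
        warning(sprintf("subject %s missing trials for pair %s->%s; skipped",
                        subj, prev, nxt), call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        from = prev, to = nxt, pair = paste0(prev, "->", nxt),
        subject = subj, diff_s = d_next - d_prev, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      pair = character(0), subject = character(0),
                      diff_s = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Percentile bootstrap CI for a mean paired difference
#'
#' Resamples subjects with replacement `n_boot` times and reports the mean
#' of the per-subject differences with a percentile confidence interval of
#' the bootstrap means (2.5th/97.5th percentiles at the default 95% level),
#' plus the bootstrap-distribution median. Deterministic given `seed`.
#'
#' @param diffs Numeric vector of per-subject differences (seconds).
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed (required).
#' @return A list of class `ohd_effect` with `point_s`, `ci_low_s`,
#'   `ci_high_s`, `boot_median_s`, `n_subjects`, `n_boot`, `level`, `seed`.
#' @export
bootstrap_ci <- function(diffs, n_boot = 10000L, level = 0.95, seed) {
  if (length(diffs) == 0L) stop("no differences supplied", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (!(level > 0 && level < 1)) stop("level must be in (0,1)", call. = FALSE)
  n <- length(diffs)
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  boot_means <- rowMeans(matrix(diffs[idx], nrow = n_boot, ncol = n))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boot_means, probs = c(alpha, 1 - alpha), names = FALSE)
  structure(list(point_s = mean(diffs), ci_low_s = ci[1], ci_high_s = ci[2],
                 boot_median_s = stats::median(boot_means),
                 n_subjects = n, n_boot = as.integer(n_boot),
                 level = level, seed = as.integer(seed)),
            class = "ohd_effect")
}

#' @export
print.ohd_effect <- function(x, ...) {
  cat(sprintf("effect %.3f s  [%.3f, %.3f] %d%% CI  (n=%d, B=%d)\n",
              x$point_s, x$ci_low_s, x$ci_high_s, round(100 * x$level),
              x$n_subjects, x$n_boot))
  invisible(x)
}

#' Sign-flip permutation test for paired differences
#'
#' Tests the null of a symmetric zero-centred distribution of per-subject
#' differences by flipping the sign of each difference. When the full set of
#' `2^n` sign assignments does not exceed `n_perm`, they are enumerated
#' exactly (p = proportion of assignments with `|mean*| >= |mean|`);
#' otherwise `n_perm` random flips are drawn and
#' `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param diffs Numeric vector of per-subject differences.
#' @param n_perm Number of random permutations when enumeration is not used.
#' @param seed Integer seed (required for the Monte-Carlo branch).
#' @return A list with `p_value`, `exact` (logical), `n_used`.
#' @export
paired_permutation_test <- function(diffs, n_perm = 10000L, seed = NULL) {
  n <- length(diffs)
  if (n == 0L) stop("no differences supplied", call. = FALSE)
  obs <- abs(mean(diffs))
  tol <- 1e-12 * max(1, obs)
  if (2^n <= n_perm) {
    m <- as.integer(2^n)
    signs <- matrix(1, m, n)
    for (j in seq_len(n))
      signs[, j] <- ifelse(bitwAnd(0:(m - 1L), bitwShiftL(1L, j - 1L)) > 0L,
                           -1, 1)
    perm_means <- abs(as.numeric(signs %*% diffs)) / n
    p <- mean(perm_means >= obs - tol)
    return(list(p_value = p, exact = TRUE, n_used = m))
  }
  if (is.null(seed)) stop("a seed is required for Monte-Carlo permutation",
                          call. = FALSE)
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
  perm_means <- abs(as.numeric(flips %*% diffs)) / n
  p <- (1 + sum(perm_means >= obs - tol)) / (1 + n_perm)
  list(p_value = p, exact = FALSE, n_used = as.integer(n_perm))
}

#' Holm step-down adjustment of p-values
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

#' All habituation and dishabituation effects for a score table
#'
#' Convenience wrapper computing, for every stimulus, the habituation effect
#' (first vs final presentation) and, for every adjacent stimulus pair, the
#' dishabituation effect, each with a percentile bootstrap CI and a
#' sign-flip permutation p-value; p-values are Holm-adjusted jointly across
#' all effects.
#'
#' @inheritParams habituation_diffs
#' @inheritParams bootstrap_ci
#' @param stimulus_order Stimulus labels in presentation order.
#' @param n_perm Permutations for the p-values.
#' @return Data.frame with `kind`, `stimulus` (label or `from->to` pair),
#'   `point_s`, `boot_median_s`, `ci_low_s`, `ci_high_s`, `n`, `p_perm`,
#'   `p_holm`.
#' @export
ohd_effects <- function(scores, stimulus_order = NULL, n_boot = 10000L,
                        level = 0.95, n_perm = 10000L, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(stimulus_order)) stimulus_order <- unique(scores$stimulus)
  hab <- habituation_diffs(scores)
  dis <- dishabituation_diffs(scores, stimulus_order)
  rows <- list(); k <- 0L
  for (stim in stimulus_order) {
    d <- hab$diff_s[hab$stimulus == stim]
    if (length(d) == 0L) next
    k <- k + 1L
    est <- bootstrap_ci(d, n_boot = n_boot, level = level, seed = seed + k)
    pt <- paired_permutation_test(d, n_perm = n_perm, seed = seed + 100L + k)
    rows[[k]] <- data.frame(kind = "habituation", stimulus = stim,
                            point_s = est$point_s,
                            boot_median_s = est$boot_median_s,
                            ci_low_s = est$ci_low_s, ci_high_s = est$ci_high_s,
                            n = est$n_subjects, p_perm = pt$p_value,
                            stringsAsFactors = FALSE)
  }
  for (pair in unique(dis$pair)) {
    d <- dis$diff_s[dis$pair == pair]
    if (length(d) == 0L) next
    k <- k + 1L
    est <- bootstrap_ci(d, n_boot = n_boot, level = level, seed = seed + k)
    pt <- paired_permutation_test(d, n_perm = n_perm, seed = seed + 100L + k)
    rows[[k]] <- data.frame(kind = "dishabituation", stimulus = pair,
                            point_s = est$point_s,
                            boot_median_s = est$boot_median_s,
                            ci_low_s = est$ci_low_s, ci_high_s = est$ci_high_s,
                            n = est$n_subjects, p_perm = pt$p_value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_perm)
  out
}

#' Export a model-ready long-format score table
#'
#' Writes the trial scores as a long-format CSV
#' (`subject,session,method,stimulus,presentation,duration_s`) for external
#' mixed-model fitting. By default the table is restricted to the first and
#' third presentations, the contrast the habituation/dishabituation analysis
#' uses; pass `presentations = NULL` for the full table.
#'
#' @param scores Trial-score data.frame.
#' @param path Output CSV path.
#' @param presentations Presentations to keep, default `c(1, 3)`; `NULL`
#'   keeps all.
#' @return The exported data.frame, invisibly.
#' @export
export_long_table <- function(scores, path, presentations = c(1L, 3L)) {
  cols <- c("subject", "session", "method", "stimulus", "presentation",
            "duration_s")
  missing_cols <- setdiff(cols, names(scores))
  for (col in missing_cols) scores[[col]] <- NA
  out <- scores[, cols]
  if (!is.null(presentations))
    out <- out[out$presentation %in% presentations, , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
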