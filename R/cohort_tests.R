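#' Cohort descriptive tests
#'
#' The standard battery of group comparisons reported alongside the models:
#' \itemize{
#'   \item chi-squared test of excluded vs analysed swipes by group (2x2,
#'     with Yates continuity correction);
#'   \item chi-squared test of sex by group (2x2, Yates-corrected);
#'   \item chi-squared test of the distance-category distribution by group;
#'   \item two-sample t-tests (pooled variance) for age and for swipes per
#'     participant, and an F variance-ratio test for age;
#'   \item Mann-Whitney test of the swipe-level distance category by group.
#' }
#' When a contingency table has an empty cell, Fisher's exact test is used
#' instead and flagged in the `note` column.
#'
#' @param kin Retained swipe-level table with `participant_id`, `dist_cat`
#'   and `group` columns.
#' @param participants Participant table (retained participants) with
#'   `group`, `age_months` and optionally `sex`.
#' @param report Optional `exclusion_report` whose table carries a `group`
#'   column, for the exclusion-by-group test.
#' @return A tibble with `test`, `statistic`, `df`, `p`, `note`; the raw
#'   `htest` objects are attached as attribute `"tests"`.
#' @export
cohort_tests <- function(kin, participants, report = NULL) {
  tests <- list()
  res <- list()
  add <- function(name, ht, note = NA_character_) {
    ht <- tryCatch(ht, error = function(e) e)
    if (inherits(ht, "error")) {
      # degenerate data (e.g. constant values) yields NA, not a hard failure
      res[[length(res) + 1]] <<- tibble(test = name, statistic = NA_real_,
                                        df = NA_real_, p = NA_real_,
                                        note = conditionMessage(ht))
      return(invisible(NULL))
    }
    stat <- if (length(ht$statistic)) unname(ht$statistic) else NA_real_
    df <- if (!is.null(ht$parameter)) unname(ht$parameter[1]) else NA_real_
    res[[length(res) + 1]] <<- tibble(test = name, statistic = stat, df = df,
                                      p = ht$p.value, note = note)
    tests[[name]] <<- ht
  }
  safe_chisq <- function(name, tab, correct = TRUE) {
    if (any(tab == 0)) {
      add(name, stats::fisher.test(tab), note = "empty cell: Fisher exact")
    } else {
      add(name, suppressWarnings(chisq.test(tab, correct = correct)))
    }
  }

  if (!is.null(report) && "group" %in% names(report$table)) {
    tab <- table(excluded = !is.na(report$table$reason), group = report$table$group)
    safe_chisq("exclusion_by_group", tab)
  }
  if ("sex" %in% names(participants)) {
    safe_chisq("sex_by_group", table(participants$sex, participants$group))
  }
  safe_chisq("dist_by_group", table(kin$dist_cat, kin$group), correct = FALSE)

  age <- participants$age_months / 12
  add("age_t", t.test(age ~ participants$group, var.equal = TRUE))
  add("age_var_F", var.test(age ~ participants$group))

  spp <- kin |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  add("swipes_per_participant_t", t.test(n ~ group, data = spp, var.equal = TRUE))

  add("dist_median_mw",
      suppressWarnings(wilcox.test(as.integer(kin$dist_cat) ~ kin$group)))

  out <- dplyr::bind_rows(res)
  attr(out, "tests") <- tests
  out
}
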