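test_that("each exclusion rule fires on its designed violation", {
  fx <- make_filter_fixture()
  rep <- apply_swipe_exclusions(fx$kin)
  counts <- rep$counts
  for (rule in names(fx$hits)) {
    expect_equal(counts$n[counts$reason == rule], unname(fx$hits[rule]),
                 info = rule)
  }
  expect_equal(nrow(rep$retained), fx$n_retained)
  expect_equal(counts$n[counts$reason == "retained"], fx$n_retained)
  # conservation: every swipe is either retained or excluded exactly once
  expect_equal(sum(counts$n), nrow(fx$kin))
  # by-group columns also conserve
  expect_equal(counts$n_TD + counts$n_ASD, counts$n)
})

test_that("the cascade assigns only the first matching reason", {
  fx <- make_filter_fixture()
  kin <- fx$kin
  # one swipe violating several rules at once: multiple_touch must win
  kin$validity[200] <- "multiple_touch"
  kin$mt[200] <- 3
  kin$straightness[200] <- 2
  rep <- apply_swipe_exclusions(kin)
  reason <- rep$table$reason[rep$table$gesture_id == kin$gesture_id[200]]
  expect_equal(reason, "multiple_touch")

  # mt beats straightness when both are violated
  kin2 <- fx$kin
  kin2$mt[210] <- 3; kin2$straightness[210] <- 2
  rep2 <- apply_swipe_exclusions(kin2)
  expect_equal(rep2$table$reason[rep2$table$gesture_id == kin2$gesture_id[210]],
               "mt_outlier")

  # NA kinematics fall through to not_computable, not to an outlier rule
  kin3 <- fx$kin
  kin3$mt[220] <- NA; kin3$flagged[220] <- TRUE
  rep3 <- apply_swipe_exclusions(kin3)
  expect_equal(rep3$table$reason[rep3$table$gesture_id == kin3$gesture_id[220]],
               "not_computable")
})

test_that("participant inclusion keeps the 10% boundary and drops below it", {
  kin <- tibble::tibble(
    participant_id = rep(c("lo", "edge", "hi"), each = 20),
    goal_directed = c(rep(TRUE, 1), rep(FALSE, 19),    # 5%  -> excluded
                      rep(TRUE, 2), rep(FALSE, 18),    # 10% -> retained
                      rep(TRUE, 15), rep(FALSE, 5))    # 75% -> retained
  )
  inc <- apply_participant_inclusion(participant_swipe_counts(kin))
  expect_setequal(inc$participant_id[inc$retained], c("edge", "hi"))
  expect_equal(inc$reason[inc$participant_id == "lo"], "low_goal_directed_ratio")
  expect_equal(inc$ratio[inc$participant_id == "edge"], 0.10)
})

test_that("the literal participant rule inverts the retained set", {
  kin <- tibble::tibble(
    participant_id = rep(c("lo", "hi"), each = 20),
    goal_directed = c(rep(TRUE, 1), rep(FALSE, 19),
                      rep(TRUE, 15), rep(FALSE, 5))
  )
  lit <- apply_participant_inclusion(
    participant_swipe_counts(kin),
    filter_params(literal_participant_rule = TRUE))
  expect_setequal(lit$participant_id[lit$retained], "lo")
})

test_that("participants with no swipes are excluded with their own reason", {
  kin <- tibble::tibble(participant_id = "a", goal_directed = TRUE)
  counts <- participant_swipe_counts(
    kin, participants = tibble::tibble(participant_id = c("a", "ghost")))
  inc <- apply_participant_inclusion(counts)
  expect_false(inc$retained[inc$participant_id == "ghost"])
  expect_equal(inc$reason[inc$participant_id == "ghost"], "no_swipes")
  expect_true(inc$retained[inc$participant_id == "a"])
})

test_that("sensitivity subset drops swipes at or above the 5 mm margin", {
  fx <- make_filter_fixture()
  kin <- fx$kin
  kin$pre_first_min_dist[1:15] <- 7
  kin$post_last_min_dist[16:25] <- 6.2
  sub <- sensitivity_subset(kin)
  expect_equal(nrow(sub), nrow(kin) - 25)
  # the margin is strict: exactly 5 mm is dropped, just under passes
  kin$pre_first_min_dist[30] <- 5
  kin$pre_first_min_dist[31] <- 4.999
  sub2 <- sensitivity_subset(kin)
  expect_false(kin$gesture_id[30] %in% sub2$gesture_id)
  expect_true(kin$gesture_id[31] %in% sub2$gesture_id)
  # NA margins (features not computable) are not dropped here
  kin$pre_first_min_dist[40] <- NA
  expect_true(kin$gesture_id[40] %in% sensitivity_subset(kin)$gesture_id)
})

test_that("thresholds sit at the documented defaults and are adjustable", {
  p <- filter_params()
  expect_equal(p$mt_max, 2.0)
  expect_equal(p$dist_max, 70)
  expect_equal(p$dist_min, 13.5)
  expect_equal(p$straightness_max, 1.5)
  expect_equal(p$min_samples, 5)
  expect_equal(p$participant_goal_ratio, 0.10)
  expect_error(filter_params(mt_max = -1), "positive")

  fx <- make_filter_fixture()
  # loosening mt_max to 3 re-admits the 40 movement-time violators
  loose <- apply_swipe_exclusions(fx$kin, filter_params(mt_max = 3))
  expect_equal(nrow(loose$retained), fx$n_retained + 40)
})

test_that("the full cohort filter composes swipe and participant rules", {
  fx <- make_filter_fixture()
  kin <- fx$kin
  # participant p01 becomes non-goal-directed in 95% of swipes
  kin$goal_directed[kin$participant_id == "p01"][1:48] <- FALSE
  out <- apply_cohort_filter(kin)
  expect_false("p01" %in% out$participants$participant_id[out$participants$retained])
  expect_false("p01" %in% out$retained$participant_id)
  # retained rows are goal-directed and pass every swipe rule
  expect_true(all(out$retained$goal_directed))
  expect_true(all(out$retained$mt <= 2 & out$retained$straightness <= 1.5))
})

test_that("exclusion report serialises to JSON and prints", {
  fx <- make_filter_fixture()
  rep <- apply_swipe_exclusions(fx$kin)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_exclusion_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sum(back$counts$n), 500)
  expect_equal(back$params$mt_max, 2)
  expect_output(print(rep), "retained")
})
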