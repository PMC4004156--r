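two_tier <- function(required = 3) {
  workflow_def(list(
    task_tier("presence", "ad_presence", required,
              routes = list(route("absent", "FILTER"),
                            route("NO_CONSENSUS", "ESCALATE"),
                            route("present", "brand"))),
    task_tier("brand", "brand", required,
              routes = list(route("NO_CONSENSUS", "ESCALATE"),
                            route("*", "RESOLVE")))))
}

test_that("routing follows the first matching condition", {
  wf <- two_tier()
  item <- list(photo_id = "p1", tier_id = "presence", status = "pending",
               history = list())

  filtered <- route_next(item, majority_vote(rep("absent", 3)), wf)
  expect_equal(filtered$status, "filtered_out")

  escalated <- route_next(item, majority_vote(c("a", "a", "b", "b")), wf)
  expect_equal(escalated$status, "escalated")

  advanced <- route_next(item, majority_vote(rep("present", 3)), wf)
  expect_equal(advanced$status, "pending")
  expect_equal(advanced$tier_id, "brand")

  resolved <- route_next(list(photo_id = "p1", tier_id = "brand",
                              status = "pending", history = list()),
                         majority_vote(rep("Newport", 3)), wf)
  expect_equal(resolved$status, "resolved")
})

test_that("incomplete routing tables are rejected", {
  # constructor-level: no NO_CONSENSUS handler
  expect_error(task_tier("t", "q", routes = list(route("absent", "FILTER"))),
               "routing table incomplete")
  # runtime: decision with no matching route
  wf <- workflow_def(list(task_tier(
    "t", "q", routes = list(route("absent", "FILTER"),
                            route("NO_CONSENSUS", "ESCALATE")))))
  item <- list(photo_id = "p", tier_id = "t", status = "pending",
               history = list())
  expect_error(route_next(item, majority_vote(rep("present", 3)), wf),
               "routing table incomplete")
})

test_that("cyclic and malformed tier graphs fail at load time", {
  t1 <- task_tier("a", "q1", routes = list(route("NO_CONSENSUS", "ESCALATE"),
                                           route("*", "b")))
  t2 <- task_tier("b", "q2", routes = list(route("NO_CONSENSUS", "ESCALATE"),
                                           route("*", "a")))
  expect_error(workflow_def(list(t1, t2)), "cycle")
  expect_error(workflow_def(list(t1)), "unknown tier")
  expect_error(workflow_def(list(t1, t1)), "duplicate")
})

test_that("prevalence-0 studies are fully filtered with no downstream tasks", {
  study <- generate_study(sim_config(
    n_photos = 25, n_raters = 3, sensitivity = 1, specificity = 1, seed = 50,
    features = data.frame(feature_id = "ad_presence", prevalence = 1e-9)))
  stopifnot(all(study$gold$truth == "absent"))
  ratings <- simulate_binary_ratings(study, "ad_presence", seed = 51)
  ratings$answer[ratings$question_id == "brand"] <- "X"  # no-op guard
  run <- run_workflow(study$photos$photo_id, ratings, two_tier())
  expect_true(all(run$items$status == "filtered_out"))
  expect_false("brand" %in% names(run$task_counts))
  expect_equal(sum(run$items$n_tasks), 25)
})

test_that("prevalence-1 studies with perfect raters resolve with brand answers", {
  study <- generate_study(sim_config(
    n_photos = 20, n_raters = 3, sensitivity = 1, specificity = 1, seed = 52,
    features = data.frame(feature_id = "ad_presence", prevalence = 1.0)))
  presence <- simulate_binary_ratings(study, "ad_presence", seed = 53)
  brand <- presence
  brand$question_id <- "brand"; brand$answer <- "Newport"
  run <- run_workflow(study$photos$photo_id, rbind(presence, brand),
                      two_tier())
  expect_true(all(run$items$status == "resolved"))
  expect_equal(unname(run$task_counts["brand"]), 20)
  brand_decisions <- run$audit$decision[run$audit$tier_id == "brand"]
  expect_true(all(brand_decisions == "Newport"))
})

test_that("statuses are conserved and child tasks match the positives under perfect raters", {
  study <- generate_study(sim_config(
    n_photos = 400, n_raters = 5, sensitivity = 1, specificity = 1, seed = 54,
    features = data.frame(feature_id = "ad_presence", prevalence = 0.4)))
  presence <- simulate_binary_ratings(study, "ad_presence", seed = 55)
  brand <- presence; brand$question_id <- "brand"; brand$answer <- "B"
  run <- run_workflow(study$photos$photo_id, rbind(presence, brand),
                      two_tier(5))
  tab <- table(run$items$status)
  expect_equal(sum(tab), 400)
  n_true_pos <- sum(study$gold$truth == "present")
  expect_equal(unname(run$task_counts["brand"]), n_true_pos)
  expect_equal(unname(tab["resolved"]), n_true_pos)
  expect_equal(unname(tab["filtered_out"]), 400 - n_true_pos)
})

test_that("noisy runs conserve photos and the audit log replays to the final state", {
  study <- generate_study(sim_config(
    n_photos = 120, n_raters = 6, sensitivity = 0.7, specificity = 0.7,
    seed = 56))
  presence <- simulate_binary_ratings(study, "ad_presence", seed = 57)
  brand <- presence; brand$question_id <- "brand"
  brand$answer <- ifelse(brand$answer == "present", "A", "B")
  wf <- workflow_def(list(
    task_tier("presence", "ad_presence", 4,   # even crowd: ties occur
              routes = list(route("absent", "FILTER"),
                            route("NO_CONSENSUS", "ESCALATE"),
                            route("present", "brand"))),
    task_tier("brand", "brand", 4,
              rule = list(type = "supermajority", threshold = 0.75),
              routes = list(route("NO_CONSENSUS", "ESCALATE"),
                            route("*", "RESOLVE")))))
  run <- run_workflow(study$photos$photo_id, rbind(presence, brand), wf)

  tab <- table(factor(run$items$status,
                      c("resolved", "escalated", "filtered_out")))
  expect_equal(sum(tab), 120)
  expect_true(all(tab > 0))  # all three outcomes exercised

  # replay: the last audit outcome per photo is that photo's final status
  last <- tapply(seq_len(nrow(run$audit)), run$audit$photo_id, max)
  replayed <- run$audit$outcome[last]
  names(replayed) <- run$audit$photo_id[last]
  expect_equal(unname(replayed[run$items$photo_id]), run$items$status)

  # determinism given the same ratings stream
  run2 <- run_workflow(study$photos$photo_id, rbind(presence, brand), wf)
  expect_identical(run$items, run2$items)
  expect_identical(run$audit, run2$audit)
})

test_that("workflow definitions round-trip through YAML", {
  yaml_text <- c(
    "start: presence",
    "tiers:",
    "  presence:",
    "    question: ad_presence",
    "    required_raters: 3",
    "    rule: {type: plurality}",
    "    routes:",
    "      - {when: absent, to: FILTER}",
    "      - {when: NO_CONSENSUS, to: ESCALATE}",
    "      - {when: '*', to: brand}",
    "  brand:",
    "    question: brand",
    "    required_raters: 3",
    "    routes:",
    "      - {when: NO_CONSENSUS, to: ESCALATE}",
    "      - {when: '*', to: RESOLVE}",
    "payment: {base_rate: 0.05, multiplier: 2}")
  path <- tempfile(fileext = ".yaml")
  writeLines(yaml_text, path)
  loaded <- read_workflow(path)
  expect_s3_class(loaded$workflow, "workflow_def")
  expect_equal(loaded$workflow$start, "presence")
  expect_equal(loaded$payment$multiplier, 2)
  expect_equal(loaded$workflow$tiers$brand$required_raters, 3)
  unlink(path)
})

test_that("reverse-crop masking is idempotent and counts union area once", {
  photo <- list(photo_id = "p1", width_px = 100, height_px = 100)
  empty <- apply_reverse_crop(photo, data.frame())
  expect_equal(empty$masked_area, 0)
  expect_equal(empty$visible_area, 100 * 100)

  two <- data.frame(x0 = c(0, 5), y0 = c(0, 5), x1 = c(10, 15),
                    y1 = c(10, 15))
  masked <- apply_reverse_crop(photo, two, reveal_toggle = TRUE)
  expect_equal(masked$masked_area, 100 + 100 - 25)  # inclusion-exclusion
  expect_true(masked$revealable)
  expect_equal(masked$visible_area, 10000 - 175)

  # same box twice: identical mask
  dup <- apply_reverse_crop(photo, rbind(two, two[1, ]))
  expect_equal(dup$masked_area, masked$masked_area)
  expect_equal(nrow(dup$mask), 2)

  # masking never increases visible area; monotone across rounds
  grow <- data.frame(x0 = c(0, 5, 50), y0 = c(0, 5, 50),
                     x1 = c(10, 15, 60), y1 = c(10, 15, 60))
  areas <- vapply(1:3, function(r)
    apply_reverse_crop(photo, grow[1:r, ])$masked_area, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_true(all(areas <= 10000))

  expect_error(apply_reverse_crop(photo,
                                  data.frame(x0 = 0, y0 = 0, x1 = 200, y1 = 5)),
               "width")
})

test_that("discovery deduplication assigns first rounds and redundancy", {
  b <- function(x, r) data.frame(x0 = x, y0 = 0, x1 = x + 10, y1 = 10,
                                 tag = "ad", rater_id = r)
  # the same item found in rounds 1 and 2; a second item only in round 3
  led <- deduplicate_discoveries(list(b(0, "r1"), b(1, "r2"), b(100, "r3")))
  led_cl <- led$clusters[order(led$clusters$discovery_round), ]
  expect_equal(nrow(led_cl), 2)
  expect_equal(led_cl$discovery_round, c(1L, 3L))
  expect_equal(led_cl$redundancy, c(1L, 0L))
  expect_equal(led$members$credited, c(TRUE, FALSE, TRUE))
})

test_that("deduplication matches a brute-force cluster-and-match oracle", {
  set.seed(58)
  for (rep in 1:10) {
    truth <- data.frame(x0 = seq(0, 800, by = 200), y0 = 0)
    truth$x1 <- truth$x0 + 60; truth$y1 <- 60
    rounds <- lapply(1:3, function(r) {
      keep <- runif(5) < 0.7
      if (!any(keep)) keep[1] <- TRUE
      d <- truth[keep, ]
      d$x0 <- pmax(0, d$x0 + rnorm(nrow(d), 0, 3))
      d$x1 <- d$x1 + rnorm(nrow(d), 0, 3)
      d$y0 <- pmax(0, d$y0 + rnorm(nrow(d), 0, 3))
      d$y1 <- d$y1 + rnorm(nrow(d), 0, 3)
      d$tag <- "ad"; d$rater_id <- paste0("r", r)
      d
    })
    led <- deduplicate_discoveries(rounds, 0.5)

    all_boxes <- do.call(rbind, lapply(1:3, function(r)
      cbind(rounds[[r]], round = r)))
    comp <- bf_components(all_boxes, 0.5)
    oracle_first <- tapply(all_boxes$round, comp, min)
    expect_equal(nrow(led$clusters), length(unique(comp)))
    expect_equal(sort(as.integer(led$clusters$discovery_round)),
                 sort(as.integer(oracle_first)))
    expect_equal(sum(led$clusters$redundancy), sum(!led$members$credited))
  }
})

test_that("payments are graded geometrically by discovery round", {
  b <- function(x, r) data.frame(x0 = x, y0 = 0, x1 = x + 10, y1 = 10,
                                 tag = "ad", rater_id = r)
  # r1 discovers item A in round 1; r2 redundantly refinds A in round 2;
  # r3 discovers item B in round 3
  led <- deduplicate_discoveries(list(b(0, "r1"), b(1, "r2"), b(100, "r3")))
  pay <- compute_payment(led, base_rate = 0.05, multiplier = 2)
  expect_equal(pay$payment[pay$rater_id == "r1"], 0.05)        # round 1: 1x
  expect_equal(pay$payment[pay$rater_id == "r2"], 0.05)        # redundant
  expect_equal(pay$payment[pay$rater_id == "r3"], 0.05 * 4)    # round 3: m^2
  expect_true(all(pay$payment >= 0.05))

  # everyone discovering in round 1 earns exactly the base rate
  led1 <- deduplicate_discoveries(list(rbind(b(0, "r1"), b(100, "r2"))))
  pay1 <- compute_payment(led1, base_rate = 0.10, multiplier = 3)
  expect_equal(pay1$payment, c(0.10, 0.10))

  empty <- deduplicate_discoveries(list(data.frame()))
  expect_equal(nrow(compute_payment(empty)), 0)
  expect_error(compute_payment(led, base_rate = -1), "positive")
  expect_error(compute_payment(led, multiplier = 0.5), ">= 1")
})
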