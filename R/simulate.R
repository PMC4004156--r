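#' Configuration for a synthetic annotation study
#'
#' Defines the conditions of a simulated crowdsourcing study: how many
#' photos and raters, the prevalence of each binary target feature, the
#' rater accuracy distribution, and the noise processes for price
#' readings and crop boxes. Defaults mirror a reference calibration
#' design: a pool of 500 raters all rating the same 8 retail
#' photographs, with moderately accurate raters
#' (sensitivity = specificity = 0.75).
#'
#' @param n_photos number of photos (> 0). Default 8.
#' @param n_raters size of the rater pool (>= 2). Default 500.
#' @param features data frame with columns `feature_id` and `prevalence`
#'   (each prevalence in (0, 1\], the probability a photo truly shows the
#'   feature). Default a single `"ad_presence"` feature at prevalence 0.5.
#' @param sensitivity,specificity mean per-rater probability of a correct
#'   "present" (resp. "absent") report. Default 0.75 each; these are
#'   working defaults for an untrained crowd, not estimates of any real
#'   rater pool.
#' @param rater_sd between-rater SD of sensitivity and specificity
#'   (values are drawn from a normal and clamped to \[0, 1\]); 0 gives a
#'   homogeneous pool. Default 0.
#' @param true_price,distractor_price the true lowest tobacco price on
#'   each photo and the salient low price of a non-target product that
#'   careless raters report instead. Defaults $6.34 and $2.59.
#' @param price_noise_sd SD of Gaussian reading noise on prices, in
#'   currency units. Default 0.45.
#' @param distractor_rate probability a rater reports the distractor
#'   price instead of the true one. Default 0 (the cropped-image
#'   condition, in which the distractor is not visible).
#' @param crop_jitter_sd SD in pixels of independent Gaussian jitter on
#'   each edge of a reported crop box. Default 5.
#' @param width_px,height_px photo frame in pixels. Default 1024 x 768.
#' @param seed integer RNG seed; the whole study is a deterministic
#'   function of the configuration including the seed.
#' @return object of class `sim_config` (a validated list).
#' @seealso [generate_study()]
#' @export
sim_config <- function(n_photos = 8, n_raters = 500,
                       features = data.frame(feature_id = "ad_presence",
                                             prevalence = 0.5),
                       sensitivity = 0.75, specificity = 0.75,
                       rater_sd = 0,
                       true_price = 6.34, distractor_price = 2.59,
                       price_noise_sd = 0.45, distractor_rate = 0,
                       crop_jitter_sd = 5,
                       width_px = 1024, height_px = 768,
                       seed = 1) {
  if (n_photos < 1) stop_pc("n_photos must be positive")
  if (n_raters < 2) stop_pc("n_raters must be at least 2")
  if (!all(c("feature_id", "prevalence") %in% names(features)))
    stop_pc("features needs columns feature_id and prevalence")
  if (any(features$prevalence <= 0 | features$prevalence > 1))
    stop_pc("prevalence must be in (0, 1]")
  for (p in c(sensitivity, specificity, distractor_rate))
    if (p < 0 || p > 1) stop_pc("probabilities must be in [0, 1]")
  if (rater_sd < 0 || price_noise_sd < 0 || crop_jitter_sd < 0)
    stop_pc("noise SDs must be nonnegative")
  if (true_price < 0 || distractor_price < 0)
    stop_pc("prices must be nonnegative")
  structure(list(
    n_photos = as.integer(n_photos), n_raters = as.integer(n_raters),
    features = data.frame(feature_id = as.character(features$feature_id),
                          prevalence = as.numeric(features$prevalence)),
    sensitivity = sensitivity, specificity = specificity,
    rater_sd = rater_sd,
    true_price = true_price, distractor_price = distractor_price,
    price_noise_sd = price_noise_sd, distractor_rate = distractor_rate,
    crop_jitter_sd = crop_jitter_sd,
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    seed = as.integer(seed)
  ), class = "sim_config")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic annotation study
#'
#' Draws photos (with true feature assignments, a true price and a true
#' crop box each) and a pool of raters with heterogeneous
#' sensitivity/specificity from a [sim_config()]. The output is fully
#' determined by the configuration, seed included.
#'
#' @param config a [sim_config()].
#' @return object of class `photo_study`: list with
#'   `photos` (photo_id, width_px, height_px, true_price,
#'   distractor_price), `gold` (photo_id, feature_id, truth in
#'   present/absent), `gold_crops` (one true box per photo),
#'   `raters` (per-rater profiles) and the `config`.
#' @examples
#' study <- generate_study(sim_config(n_photos = 4, n_raters = 10, seed = 7))
#' head(study$gold)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    photos <- data.frame(
      photo_id = sprintf("photo_%04d", seq_len(config$n_photos)),
      width_px = config$width_px, height_px = config$height_px,
      true_price = config$true_price,
      distractor_price = config$distractor_price,
      stringsAsFactors = FALSE)

    gold <- do.call(rbind, lapply(seq_len(nrow(config$features)), function(i) {
      f <- config$features[i, ]
      data.frame(photo_id = photos$photo_id,
                 feature_id = f$feature_id,
                 truth = ifelse(stats::runif(config$n_photos) < f$prevalence,
                                "present", "absent"),
                 stringsAsFactors = FALSE)
    }))

    bw <- max(2, round(config$width_px / 4))
    bh <- max(2, round(config$height_px / 4))
    x0 <- floor(stats::runif(config$n_photos, 0, config$width_px - bw))
    y0 <- floor(stats::runif(config$n_photos, 0, config$height_px - bh))
    gold_crops <- data.frame(photo_id = photos$photo_id,
                             tag = "ad",
                             x0 = x0, y0 = y0, x1 = x0 + bw, y1 = y0 + bh,
                             stringsAsFactors = FALSE)

    raters <- data.frame(
      rater_id = sprintf("rater_%04d", seq_len(config$n_raters)),
      sensitivity = clamp01(stats::rnorm(config$n_raters, config$sensitivity,
                                         config$rater_sd)),
      specificity = clamp01(stats::rnorm(config$n_raters, config$specificity,
                                         config$rater_sd)),
      price_noise_sd = config$price_noise_sd,
      distractor_rate = config$distractor_rate,
      crop_jitter_sd = config$crop_jitter_sd,
      stringsAsFactors = FALSE)

    structure(list(photos = photos, gold = gold, gold_crops = gold_crops,
                   raters = raters, config = config),
              class = "photo_study")
  })
}

#' @export
print.photo_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic annotation study: %d photos, %d raters, %d feature(s) [seed %d]\n",
    nrow(x$photos), nrow(x$raters), nrow(x$config$features), x$config$seed))
  invisible(x)
}

#' Simulate a complete set of binary ratings
#'
#' Every rater rates every photo for one binary feature (a complete
#' design). For a truly positive photo a rater reports "present" with
#' probability equal to their sensitivity; for a negative photo they
#' report "absent" with probability equal to their specificity. Errors
#' are independent across raters and photos.
#'
#' @param study a [generate_study()] result.
#' @param feature_id which feature to rate (must exist in the study's
#'   gold standard).
#' @param seed integer seed for the rating noise.
#' @return ratings data frame: `photo_id, rater_id, task_id,
#'   question_id, answer_type, answer, timestamp`.
#' @export
simulate_binary_ratings <- function(study, feature_id, seed = 1) {
  stopifnot(inherits(study, "photo_study"))
  gold <- study$gold[study$gold$feature_id == feature_id, ]
  if (nrow(gold) == 0) stop_pc("unknown feature: ", feature_id)
  gold <- gold[match(study$photos$photo_id, gold$photo_id), ]
  np <- nrow(study$photos); nr <- nrow(study$raters)
  local_seed(seed, {
    pos <- gold$truth == "present"
    # P(report "present") per photo x rater cell
    prob <- outer(pos, study$raters$sensitivity) +
      outer(!pos, 1 - study$raters$specificity)
    said_present <- matrix(stats::runif(np * nr) < prob, np, nr)
    data.frame(
      photo_id = rep(study$photos$photo_id, times = nr),
      rater_id = rep(study$raters$rater_id, each = np),
      task_id = paste0("task_", feature_id),
      question_id = feature_id,
      answer_type = "binary",
      answer = ifelse(as.vector(said_present), "present", "absent"),
      timestamp = NA_character_,
      stringsAsFactors = FALSE)
  })
}

#' Simulate crowd price readings
#'
#' Each rater reads the lowest advertised price on each photo. With
#' probability `distractor_rate` the rater reports the photo's salient
#' distractor price (a cheap non-target product); otherwise the true
#' price plus Gaussian reading noise, truncated at zero and rounded to
#' cents.
#'
#' @inheritParams simulate_binary_ratings
#' @return ratings data frame with `answer_type = "numeric"` and answers
#'   formatted as decimal strings with two digits.
#' @export
simulate_price_readings <- function(study, seed = 1) {
  stopifnot(inherits(study, "photo_study"))
  np <- nrow(study$photos); nr <- nrow(study$raters)
  local_seed(seed, {
    distract <- matrix(
      stats::runif(np * nr) < rep(study$raters$distractor_rate, each = np),
      np, nr)
    noise <- matrix(
      stats::rnorm(np * nr, 0, rep(study$raters$price_noise_sd, each = np)),
      np, nr)
    reading <- matrix(study$photos$true_price, np, nr) + noise
    reading[distract] <- matrix(study$photos$distractor_price, np, nr)[distract]
    reading <- round(pmax(0, reading), 2)
    data.frame(
      photo_id = rep(study$photos$photo_id, times = nr),
      rater_id = rep(study$raters$rater_id, each = np),
      task_id = "task_lowest_price",
      question_id = "lowest_price",
      answer_type = "numeric",
      answer = sprintf("%.2f", as.vector(reading)),
      timestamp = NA_character_,
      stringsAsFactors = FALSE)
  })
}

#' Simulate jittered crop boxes
#'
#' Each rater reports the study's true box per photo with independent
#' Gaussian jitter (SD `crop_jitter_sd` pixels) on each of the four
#' edges, clamped to the photo frame; a minimum extent of one pixel is
#' enforced so every reported box stays valid.
#'
#' @inheritParams simulate_binary_ratings
#' @return crops data frame: `photo_id, rater_id, task_id, tag,
#'   x0, y0, x1, y1`.
#' @export
simulate_crop_boxes <- function(study, seed = 1) {
  stopifnot(inherits(study, "photo_study"))
  gc <- study$gold_crops
  np <- nrow(gc); nr <- nrow(study$raters)
  local_seed(seed, {
    jit <- function(edge) {
      matrix(edge, np, nr) +
        matrix(stats::rnorm(np * nr, 0,
                            rep(study$raters$crop_jitter_sd, each = np)),
               np, nr)
    }
    W <- study$photos$width_px[match(gc$photo_id, study$photos$photo_id)]
    H <- study$photos$height_px[match(gc$photo_id, study$photos$photo_id)]
    x0 <- pmax(0, pmin(jit(gc$x0), W - 1))
    y0 <- pmax(0, pmin(jit(gc$y0), H - 1))
    x1 <- pmax(x0 + 1, pmin(jit(gc$x1), W))
    y1 <- pmax(y0 + 1, pmin(jit(gc$y1), H))
    data.frame(
      photo_id = rep(gc$photo_id, times = nr),
      rater_id = rep(study$raters$rater_id, each = np),
      task_id = "task_crop",
      tag = rep(gc$tag, times = nr),
      x0 = round(as.vector(x0)), y0 = round(as.vector(y0)),
      x1 = round(as.vector(x1)), y1 = round(as.vector(y1)),
      stringsAsFactors = FALSE)
  })
}

#' Exact probability that a majority vote is correct
#'
#' For an odd crowd of `n` independent raters each correct with
#' probability `p`, the majority is correct with probability
#' `P(Binomial(n, p) > n/2)`. Serves as the analytic oracle for the
#' simulation-based consensus machinery; even crowds can tie, so they
#' must go through the simulation path instead.
#'
#' @param n odd positive integer crowd size.
#' @param p per-rater accuracy in \[0, 1\].
#' @return probability in \[0, 1\].
#' @examples
#' consensus_accuracy(15, 0.8)
#' @export
consensus_accuracy <- function(n, p) {
  if (length(n) != 1 || n < 1 || n != round(n)) stop_pc("n must be a positive integer")
  if (n %% 2 == 0) stop_pc("n must be odd (even crowds can tie)")
  if (p < 0 || p > 1) stop_pc("p must be in [0, 1]")
  stats::pbinom(floor(n / 2), n, p, lower.tail = FALSE)
}

#' Reshape complete binary ratings to a photo-by-rater indicator matrix
#'
#' @param ratings ratings data frame for one binary question.
#' @param positive the answer counted as a positive report.
#' @return logical matrix, rows = photos (rownames photo_id), columns =
#'   raters (colnames rater_id). Errors unless the design is complete
#'   (every rater rated every photo exactly once).
#' @export
rating_matrix <- function(ratings, positive = "present") {
  if (length(unique(ratings$question_id)) > 1)
    stop_pc("heterogeneous input: more than one question_id")
  photos <- sort(unique(ratings$photo_id))
  raters <- sort(unique(ratings$rater_id))
  if (nrow(ratings) != length(photos) * length(raters) ||
      anyDuplicated(ratings[c("photo_id", "rater_id")]) > 0)
    stop_pc("ratings must form a complete photo x rater design")
  m <- matrix(FALSE, length(photos), length(raters),
              dimnames = list(photos, raters))
  m[cbind(match(ratings$photo_id, photos), match(ratings$rater_id, raters))] <-
    ratings$answer == positive
  m
}
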