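#' Crowd-size resampling curve
#'
#' The crowd-size calibration procedure: from a pool of raters who all
#' rated the same photos, draw many random subsamples ("jackknife"
#' subsamples, without replacement within a draw) at each candidate
#' crowd size k, score every photo by the subsample's vote fraction,
#' and measure each subsample's AUC against the gold standard. The
#' spread of AUC across subsamples at a given k shows how volatile a
#' crowd of that size is; the curve of mean AUC with pointwise
#' percentile intervals identifies the smallest crowd that reliably
#' approximates the maximum achievable accuracy.
#'
#' @param ratings complete binary ratings for one question (data frame
#'   as produced by [simulate_binary_ratings()] or [read_ratings()]), or
#'   a photo-by-rater logical matrix from [rating_matrix()].
#' @param gold gold-standard labels: a data frame with `photo_id` and
#'   `truth` columns, or a vector named by photo id, or an unnamed
#'   vector aligned with the matrix rows.
#' @param k crowd sizes to test (default `2:20`); each must be at most
#'   the pool size.
#' @param n_samples number of random subsamples per crowd size
#'   (default 50).
#' @param seed integer seed; the whole curve is deterministic given it.
#' @param positive answer counted as a positive report.
#' @param conf_level coverage of the pointwise percentile interval
#'   (default 0.95, i.e. the 2.5 and 97.5 percentiles of the resampled
#'   AUCs).
#' @return object of class `crowd_size_curve`: data frame with one row
#'   per k — `k, mean_auc, ci_lo, ci_hi, sd_auc, n_samples` — and an
#'   attribute `"auc_draws"` holding the full k x n_samples matrix of
#'   resampled AUCs.
#' @examples
#' study <- generate_study(sim_config(n_photos = 30, n_raters = 25, seed = 3))
#' r <- simulate_binary_ratings(study, "ad_presence", seed = 4)
#' crowd_size_curve(r, study$gold, k = c(2, 5, 9), n_samples = 20, seed = 5)
#' @export
crowd_size_curve <- function(ratings, gold, k = 2:20, n_samples = 50,
                             seed = 1, positive = "present",
                             conf_level = 0.95) {
  m <- if (is.matrix(ratings)) ratings else rating_matrix(ratings, positive)
  y <- align_gold(gold, rownames(m), positive)
  pool <- ncol(m)
  k <- sort(unique(as.integer(k)))
  if (any(k < 1)) stop_pc("crowd sizes must be >= 1")
  if (any(k > pool)) stop_pc("crowd size exceeds rater pool (", pool, ")")
  if (n_samples < 1) stop_pc("n_samples must be >= 1")
  if (sum(y) == 0 || sum(!y) == 0)
    stop_pc("AUC undefined: gold standard has only one class")

  alpha <- (1 - conf_level) / 2
  draws <- matrix(NA_real_, length(k), n_samples,
                  dimnames = list(k = k, NULL))
  local_seed(seed, {
    for (i in seq_along(k)) {
      for (s in seq_len(n_samples)) {
        idx <- sample.int(pool, k[i])
        score <- rowMeans(m[, idx, drop = FALSE])
        draws[i, s] <- auc(score, y)$auc
      }
    }
  })
  out <- data.frame(
    k = k,
    mean_auc = rowMeans(draws),
    ci_lo = apply(draws, 1, stats::quantile, probs = alpha, names = FALSE),
    ci_hi = apply(draws, 1, stats::quantile, probs = 1 - alpha, names = FALSE),
    sd_auc = apply(draws, 1, stats::sd),
    n_samples = n_samples)
  structure(out, class = c("crowd_size_curve", "data.frame"),
            auc_draws = draws, seed = seed, conf_level = conf_level)
}

align_gold <- function(gold, photo_ids, positive = "present") {
  if (is.data.frame(gold)) {
    if (!all(c("photo_id", "truth") %in% names(gold)))
      stop_pc("gold needs photo_id and truth columns")
    if (anyDuplicated(gold$photo_id) > 0)
      stop_pc("gold has duplicate photo ids; filter to one feature first")
    idx <- match(photo_ids, gold$photo_id)
    if (anyNA(idx)) stop_pc("gold is missing some rated photos")
    return(as_binary_labels(gold$truth[idx], positive))
  }
  if (!is.null(names(gold))) {
    idx <- match(photo_ids, names(gold))
    if (anyNA(idx)) stop_pc("gold is missing some rated photos")
    return(as_binary_labels(gold[idx], positive))
  }
  if (length(gold) != length(photo_ids))
    stop_pc("unnamed gold vector must match the number of photos")
  as_binary_labels(gold, positive)
}

#' @export
print.crowd_size_curve <- function(x, ...) {
  cat(sprintf("Crowd-size resampling curve (%d sizes, %d subsamples each)\n",
              nrow(x), x$n_samples[1]))
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' Smallest crowd size reaching a target AUC
#'
#' Scans a [crowd_size_curve()] for the smallest tested crowd size whose
#' mean AUC (criterion `"mean"`) or lower pointwise confidence bound
#' (criterion `"ci_lower"`, i.e. even the volatile subsamples clear the
#' bar) reaches `target_auc`.
#'
#' @param curve a `crowd_size_curve`.
#' @param target_auc required AUC, in (0.5, 1].
#' @param criterion `"mean"` or `"ci_lower"`.
#' @return the crowd size (integer), or `NA` if no tested size reaches
#'   the target.
#' @export
minimal_crowd_size <- function(curve, target_auc = 0.90,
                               criterion = c("mean", "ci_lower")) {
  stopifnot(inherits(curve, "crowd_size_curve"))
  if (nrow(curve) == 0) stop_pc("empty curve")
  if (target_auc <= 0.5 || target_auc > 1)
    stop_pc("target_auc must be in (0.5, 1]")
  criterion <- match.arg(criterion)
  stat <- if (criterion == "mean") curve$mean_auc else curve$ci_lo
  hit <- which(stat >= target_auc)
  if (length(hit) == 0) NA_integer_ else curve$k[min(hit)]
}

#' Crowd size at which between-sample variation stabilises
#'
#' Smallest tested crowd size from which onwards the between-subsample
#' SD of AUC stays at or below `epsilon` — the point where adding raters
#' no longer buys reliability.
#'
#' @param curve a `crowd_size_curve`.
#' @param epsilon tolerated AUC standard deviation (> 0). Default 0.02.
#' @return the crowd size (integer), or `NA` if never stabilised within
#'   the tested range.
#' @export
stabilization_point <- function(curve, epsilon = 0.02) {
  stopifnot(inherits(curve, "crowd_size_curve"))
  if (nrow(curve) == 0) stop_pc("empty curve")
  if (!is.numeric(epsilon) || epsilon <= 0) stop_pc("epsilon must be > 0")
  ok <- rev(cumprod(rev(curve$sd_auc <= epsilon))) == 1
  hit <- which(ok)
  if (length(hit) == 0) NA_integer_ else curve$k[min(hit)]
}
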