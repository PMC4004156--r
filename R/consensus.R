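#' Aggregate one photo-question's ratings into a crowd consensus
#'
#' Applies a plurality or supermajority decision rule to the binary or
#' categorical answers that independent raters gave to one question about
#' one photo. Exact ties, and pluralities below a supermajority
#' threshold, yield no consensus: the photo is then typically escalated
#' to expert review rather than decided by a coin flip.
#'
#' @param answers character vector of answers, one per rater (e.g.
#'   `"present"`/`"absent"`, or brand labels). All answers must concern
#'   the same photo and question; supplying a `ratings` data frame with
#'   more than one `photo_id`/`question_id` is an error.
#' @param rule `"plurality"` (modal answer wins unless tied) or
#'   `"supermajority"` (modal answer must reach `threshold`).
#' @param threshold required vote fraction for `rule = "supermajority"`,
#'   in (0.5, 1]. Default 2/3.
#' @param photo_id,question_id optional identifiers carried into the
#'   result for bookkeeping.
#'
#' @return An object of class `consensus_result`: a list with elements
#'   `decision` (the winning answer, or `NA` when there is no
#'   consensus), `no_consensus` (logical), `vote_fraction` (share of
#'   raters supporting `decision`; on a tie, the share of the
#'   lexicographically smallest leading answer), `n_raters`, `photo_id`,
#'   `question_id`.
#'
#' @examples
#' majority_vote(c("present", "present", "absent"))
#' majority_vote(c("a", "a", "b", "b"))           # tie -> no consensus
#' majority_vote(rep("menthol", 104))$vote_fraction
#' @export
majority_vote <- function(answers, rule = c("plurality", "supermajority"),
                          threshold = 2 / 3,
                          photo_id = NA_character_,
                          question_id = NA_character_) {
  if (is.data.frame(answers)) {
    df <- answers
    if (length(unique(df$question_id)) > 1 || length(unique(df$photo_id)) > 1)
      stop_pc("heterogeneous input: ratings span more than one photo-question")
    photo_id <- df$photo_id[1]
    question_id <- df$question_id[1]
    answers <- df$answer
  }
  if (length(answers) == 0) stop_pc("no ratings")
  if (anyNA(answers)) stop_pc("missing answers are not allowed")
  rule <- match.arg(rule)
  if (rule == "supermajority" &&
      (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1))
    stop_pc("supermajority threshold must be in (0.5, 1]")

  answers <- as.character(answers)
  tab <- table(answers)
  top <- max(tab)
  leaders <- sort(names(tab)[tab == top])   # lexicographic, deterministic
  frac <- top / length(answers)

  tie <- length(leaders) > 1
  below <- rule == "supermajority" && frac < threshold
  no_consensus <- tie || below

  structure(list(
    photo_id = photo_id,
    question_id = question_id,
    decision = if (no_consensus) NA_character_ else leaders[1],
    no_consensus = no_consensus,
    vote_fraction = frac,
    n_raters = length(answers)
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  dec <- if (x$no_consensus) "NO_CONSENSUS" else x$decision
  cat(sprintf("Consensus: %s (%d/%d raters, vote fraction %.3f)\n",
              dec, round(x$vote_fraction * x$n_raters), x$n_raters,
              x$vote_fraction))
  invisible(x)
}

#' Did the crowd fail to reach consensus?
#' @param x a `consensus_result`.
#' @return logical.
#' @export
is_no_consensus <- function(x) {
  stopifnot(inherits(x, "consensus_result"))
  isTRUE(x$no_consensus)
}

#' Vote-fraction score for a binary question
#'
#' The share of raters reporting the target present. This is the
#' continuous per-photo classifier score fed to ROC analysis when crowd
#' ratings are compared with a gold standard; thresholding it at 0.5
#' recovers the majority vote.
#'
#' @param answers character vector of binary answers.
#' @param positive the answer counted as a positive report
#'   (default `"present"`).
#' @return numeric in \[0, 1\].
#' @examples
#' vote_fraction(c(rep("present", 7), rep("absent", 93)))  # 0.07
#' @export
vote_fraction <- function(answers, positive = "present") {
  if (length(answers) == 0) stop_pc("no ratings")
  if (anyNA(answers)) stop_pc("missing answers are not allowed")
  mean(as.character(answers) == positive)
}

#' Summarise crowd price readings
#'
#' Mean, sample standard deviation (n-1 denominator; `NA` when only one
#' reading), count, and minimum of numeric price answers. In lowest-price
#' tasks the minimum is the quantity of interest and the SD measures
#' crowd agreement — e.g. a crowd reading a cropped price tag can agree
#' to the cent (SD 0.00).
#'
#' @param prices numeric vector of price readings (currency units), or a
#'   character vector parsed with [parse_price()].
#' @return An object of class `price_summary`: list with `mean`, `sd`
#'   (`NA` if `n == 1`), `n`, `min`.
#' @examples
#' aggregate_prices(c(7.29, 7.29, 7.29, 6.34))
#' @export
aggregate_prices <- function(prices) {
  if (is.character(prices)) prices <- parse_price(prices)
  if (length(prices) == 0) stop_pc("no ratings")
  if (anyNA(prices)) stop_pc("invalid price: missing or unparseable reading")
  if (any(prices < 0)) stop_pc("invalid price: negative reading")
  structure(list(
    mean = mean(prices),
    sd = if (length(prices) == 1) NA_real_ else stats::sd(prices),
    n = length(prices),
    min = min(prices)
  ), class = "price_summary")
}

#' @export
print.price_summary <- function(x, ...) {
  sd_txt <- if (is.na(x$sd)) "undefined" else sprintf("%.2f", x$sd)
  cat(sprintf("Price summary: mean $%.2f (SD %s), min $%.2f, n = %d\n",
              x$mean, sd_txt, x$min, x$n))
  invisible(x)
}

#' Parse currency strings to numeric prices
#'
#' Strips `$` and thousands separators and rounds to cents. Used when
#' reading numeric answers from ratings files.
#'
#' @param x character vector like `"$6.34"`, `"1,299.99"`.
#' @return numeric vector; unparseable entries become `NA`.
#' @export
parse_price <- function(x) {
  cleaned <- gsub("[$,]", "", trimws(as.character(x)))
  round(suppressWarnings(as.numeric(cleaned)), 2)
}

#' Pearson chi-square test of homogeneity
#'
#' Compares response distributions across study arms (e.g. the share of
#' raters identifying an advertisement with and without a zoom or crop
#' tool). No continuity correction is applied; degrees of freedom come
#' from the table shape, `(r-1)(c-1)`.
#'
#' @param counts an r x c matrix of nonnegative integer counts, r, c >= 2
#'   (rows = arms, columns = response categories).
#' @return list with `statistic`, `df`, `p_value`, and the `expected`
#'   cell counts.
#' @examples
#' chi_square_homogeneity(rbind(c(7, 93), c(73, 27), c(88, 12)))
#' @export
chi_square_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop_pc("table must be at least 2 x 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_pc("counts must be nonnegative integers")
  if (sum(counts) == 0) stop_pc("degenerate table: empty")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_pc("degenerate table: zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       expected = ht$expected)
}

#' Proportion with Wilson 95% score interval
#'
#' Point estimate and Wilson score confidence interval for a binomial
#' proportion, the standard reporting form for "x of n raters answered
#' correctly" results.
#'
#' @param successes,n nonnegative counts, `successes <= n`, `n > 0`.
#' @param conf_level confidence level (default 0.95).
#' @return list with `proportion`, `lower`, `upper`, `successes`, `n`.
#' @examples
#' proportion_ci(88, 100)
#' @export
proportion_ci <- function(successes, n, conf_level = 0.95) {
  if (length(successes) != 1 || length(n) != 1 || is.na(successes) || is.na(n))
    stop_pc("successes and n must be scalars")
  if (n <= 0) stop_pc("n must be positive")
  if (successes < 0 || successes > n) stop_pc("successes must be in [0, n]")
  pt <- suppressWarnings(
    stats::prop.test(successes, n, conf.level = conf_level, correct = FALSE))
  list(proportion = successes / n,
       lower = pt$conf.int[1],
       upper = pt$conf.int[2],
       successes = successes,
       n = n)
}
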