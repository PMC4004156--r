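#' Summarise a result as a report
#'
#' Turns any stage's result — a consensus, a price summary, a two-arm
#' usability comparison, a crowd-size curve, a workflow run, a discovery
#' ledger — into a plain list suitable both for printing and for stable
#' machine-readable JSON via [write_report()]. Regenerating a report
#' from the same inputs yields byte-identical JSON.
#'
#' @param x the result to report on.
#' @param ... passed to methods.
#' @return a list of class `pc_report`.
#' @export
report <- function(x, ...) UseMethod("report")

pc_report <- function(type, body) {
  structure(c(list(type = type), body), class = "pc_report")
}

#' @export
print.pc_report <- function(x, ...) {
  cat("Report [", x$type, "]\n", sep = "")
  str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' @rdname report
#' @export
report.consensus_result <- function(x, ...) {
  pc_report("consensus", list(
    photo_id = x$photo_id, question_id = x$question_id,
    decision = if (x$no_consensus) "NO_CONSENSUS" else x$decision,
    vote_fraction = x$vote_fraction, n_raters = x$n_raters))
}

#' @rdname report
#' @export
report.price_summary <- function(x, ...) {
  pc_report("price_summary",
            list(mean = x$mean, sd = x$sd, n = x$n, min = x$min))
}

#' @rdname report
#' @param conf_level confidence level for the per-arm Wilson intervals.
#' @export
report.matrix <- function(x, conf_level = 0.95, ...) {
  # two-or-more-arm comparison: rows = arms, col 1 = successes
  ht <- chi_square_homogeneity(x)
  arms <- lapply(seq_len(nrow(x)), function(i) {
    ci <- proportion_ci(x[i, 1], sum(x[i, ]), conf_level)
    list(successes = unname(x[i, 1]), n = unname(sum(x[i, ])),
         proportion = ci$proportion, lower = ci$lower, upper = ci$upper)
  })
  names(arms) <- rownames(x) %||% paste0("arm_", seq_len(nrow(x)))
  pc_report("comparison", list(
    counts = unname(apply(x, 1, as.integer, simplify = FALSE)),
    arms = arms,
    chi_square = list(statistic = ht$statistic, df = ht$df,
                      p_value = ht$p_value)))
}

#' @rdname report
#' @export
report.crowd_size_curve <- function(x, ...) {
  pc_report("crowd_size_curve", list(
    seed = attr(x, "seed"),
    conf_level = attr(x, "conf_level"),
    sizes = lapply(seq_len(nrow(x)), function(i) as.list(as.data.frame(x)[i, ]))))
}

#' @rdname report
#' @export
report.workflow_run <- function(x, ...) {
  tab <- table(factor(x$items$status,
                      levels = c("resolved", "escalated", "filtered_out")))
  pc_report("workflow_run", list(
    n_photos = nrow(x$items),
    resolved = unname(tab["resolved"]),
    escalated = unname(tab["escalated"]),
    filtered_out = unname(tab["filtered_out"]),
    tasks_per_tier = as.list(x$task_counts),
    n_transitions = nrow(x$audit)))
}

#' @rdname report
#' @export
report.discovery_ledger <- function(x, ...) {
  pc_report("discovery_ledger", list(
    n_items = nrow(x$clusters),
    n_boxes = nrow(x$members),
    by_round = as.list(table(x$clusters$discovery_round)),
    total_redundancy = sum(x$clusters$redundancy)))
}

#' @rdname report
#' @export
report.default <- function(x, ...) {
  if (is.null(x) || (is.list(x) && length(x) == 0))
    return(pc_report("empty", list()))
  stop_pc("no report method for class ", paste(class(x), collapse = "/"))
}

#' Write a report as JSON
#'
#' @param rep a [report()] result (or a plain named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rep, path) {
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
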