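#' Build a task tier
#'
#' One node of the tiered annotation workflow: a single question posed
#' to a fixed number of raters, with routing rules applied to the
#' crowd's consensus. Decomposing annotation into such small tiers keeps
#' each task simple and lets photos flow adaptively — photos without the
#' target are filtered out before any downstream question is asked, and
#' photos the crowd cannot agree on are funneled to experts.
#'
#' @param tier_id unique tier identifier.
#' @param question_id the question asked at this tier.
#' @param required_raters number of raters whose answers are aggregated
#'   (>= 1).
#' @param rule consensus rule: list with `type`
#'   (`"plurality"`/`"supermajority"`) and optional `threshold`.
#' @param routes list of [route()] conditions, evaluated in declaration
#'   order; the first match wins. Must handle the no-consensus outcome
#'   (a `when = "NO_CONSENSUS"` or catch-all `when = "*"` entry).
#' @return object of class `task_tier`.
#' @seealso [workflow_def()], [route()]
#' @export
task_tier <- function(tier_id, question_id, required_raters = 5,
                      rule = list(type = "plurality"),
                      routes = list(route("NO_CONSENSUS", "ESCALATE"),
                                    route("*", "RESOLVE"))) {
  if (required_raters < 1) stop_pc("required_raters must be >= 1")
  if (!rule$type %in% c("plurality", "supermajority"))
    stop_pc("unknown consensus rule: ", rule$type)
  whens <- vapply(routes, function(r) r$when, character(1))
  if (!any(whens %in% c("NO_CONSENSUS", "*")))
    stop_pc("routing table incomplete: tier '", tier_id,
            "' does not handle NO_CONSENSUS")
  structure(list(tier_id = tier_id, question_id = question_id,
                 required_raters = as.integer(required_raters),
                 rule = rule, routes = routes),
            class = "task_tier")
}

#' Routing condition for a task tier
#'
#' @param when consensus decision that triggers this route: an answer
#'   value, `"NO_CONSENSUS"`, or the catch-all `"*"`.
#' @param to destination: another tier id, or one of the terminal
#'   actions `"RESOLVE"` (photo fully annotated), `"FILTER"` (photo
#'   irrelevant, drop it), `"ESCALATE"` (send to expert review).
#' @return list with elements `when` and `to`.
#' @export
route <- function(when, to) {
  list(when = as.character(when), to = as.character(to))
}

TERMINALS <- c("RESOLVE", "FILTER", "ESCALATE")

#' Assemble and validate a tiered workflow
#'
#' @param tiers list of [task_tier()] objects.
#' @param start tier id where every photo enters (default: first tier).
#' @return object of class `workflow_def`. Errors if route targets are
#'   unknown, if the tier graph has a cycle, or if a tier lacks a
#'   no-consensus route.
#' @examples
#' wf <- workflow_def(list(
#'   task_tier("presence", "ad_presence", 5,
#'             routes = list(route("absent", "FILTER"),
#'                           route("NO_CONSENSUS", "ESCALATE"),
#'                           route("present", "brand"))),
#'   task_tier("brand", "brand", 5,
#'             routes = list(route("NO_CONSENSUS", "ESCALATE"),
#'                           route("*", "RESOLVE")))))
#' @export
workflow_def <- function(tiers, start = NULL) {
  stopifnot(length(tiers) >= 1,
            all(vapply(tiers, inherits, logical(1), "task_tier")))
  ids <- vapply(tiers, function(t) t$tier_id, character(1))
  if (anyDuplicated(ids) > 0) stop_pc("duplicate tier ids")
  names(tiers) <- ids
  start <- start %||% ids[1]
  if (!start %in% ids) stop_pc("unknown start tier: ", start)
  edges <- do.call(rbind, lapply(tiers, function(t) {
    tos <- vapply(t$routes, function(r) r$to, character(1))
    tos <- setdiff(tos, TERMINALS)
    if (length(tos) == 0) return(NULL)
    data.frame(from = t$tier_id, to = tos, stringsAsFactors = FALSE)
  }))
  if (!is.null(edges)) {
    unknown <- setdiff(edges$to, ids)
    if (length(unknown) > 0)
      stop_pc("route to unknown tier: ", paste(unknown, collapse = ", "))
    g <- igraph::graph_from_data_frame(edges, vertices = data.frame(name = ids))
    if (!igraph::is_dag(g)) stop_pc("tier graph contains a cycle")
  }
  structure(list(tiers = tiers, start = start), class = "workflow_def")
}

#' @export
print.workflow_def <- function(x, ...) {
  cat(sprintf("Tiered annotation workflow: %d tier(s), entry at '%s'\n",
              length(x$tiers), x$start))
  for (t in x$tiers) {
    cat(sprintf("  [%s] asks '%s' of %d raters -> %s\n", t$tier_id,
                t$question_id, t$required_raters,
                paste(vapply(t$routes, function(r)
                  paste0(r$when, ":", r$to), character(1)), collapse = " ")))
  }
  invisible(x)
}

#' Advance one work item given a tier's consensus
#'
#' Applies the current tier's routing table to a consensus result: the
#' first condition matching the decision wins. A no-consensus outcome
#' routed to `ESCALATE` marks the photo for expert inspection; a
#' consensus of absence routed to `FILTER` drops the photo from all
#' downstream tiers.
#'
#' @param item a work item as created inside [run_workflow()]: list with
#'   `photo_id`, `tier_id`, `status`.
#' @param consensus a [majority_vote()] result for the item's current
#'   tier.
#' @param workflow the [workflow_def()].
#' @return the updated work item, with `status` one of
#'   `"pending"` (moved to a child tier), `"resolved"`, `"escalated"`,
#'   `"filtered_out"`.
#' @export
route_next <- function(item, consensus, workflow) {
  stopifnot(inherits(consensus, "consensus_result"),
            inherits(workflow, "workflow_def"))
  tier <- workflow$tiers[[item$tier_id]]
  if (is.null(tier)) stop_pc("unknown tier: ", item$tier_id)
  key <- if (is_no_consensus(consensus)) "NO_CONSENSUS" else consensus$decision
  to <- NULL
  for (r in tier$routes) {
    if (r$when == "*" || r$when == key) { to <- r$to; break }
  }
  if (is.null(to))
    stop_pc("routing table incomplete: tier '", tier$tier_id,
            "' has no route for outcome '", key, "'")
  item$history <- c(item$history, list(consensus))
  if (to %in% TERMINALS) {
    item$status <- switch(to, RESOLVE = "resolved", FILTER = "filtered_out",
                          ESCALATE = "escalated")
    item$tier_id <- NA_character_
  } else {
    item$status <- "pending"
    item$tier_id <- to
  }
  item
}

#' Run a tiered annotation workflow over a photo set
#'
#' Routes every photo through the workflow, aggregating the configured
#' number of raters' answers at each tier and applying the routing rules
#' until the photo reaches a terminal status. The run is deterministic
#' given the ratings source, and every transition is recorded in an
#' audit log that replays to the identical final state.
#'
#' @param photo_ids character vector of photos entering the workflow.
#' @param ratings either a ratings data frame covering every
#'   photo-question a tier may ask (at each tier the first
#'   `required_raters` raters in sorted `rater_id` order answer), or a
#'   function `f(photo_id, question_id, n)` returning `n` answers.
#' @param workflow a [workflow_def()].
#' @return object of class `workflow_run`: list with
#'   `items` (data frame `photo_id, status, n_tasks`),
#'   `audit` (data frame `step, photo_id, tier_id, decision,
#'   vote_fraction, outcome`), and `task_counts` (issued tasks per
#'   tier).
#' @export
run_workflow <- function(photo_ids, ratings, workflow) {
  stopifnot(inherits(workflow, "workflow_def"))
  photo_ids <- as.character(photo_ids)
  get_answers <- if (is.function(ratings)) {
    ratings
  } else {
    function(photo_id, question_id, n) {
      sub <- ratings[ratings$photo_id == photo_id &
                       ratings$question_id == question_id, , drop = FALSE]
      sub <- sub[order(sub$rater_id), , drop = FALSE]
      if (nrow(sub) < n)
        stop_pc("not enough ratings for photo ", photo_id,
                ", question ", question_id, " (need ", n, ", have ",
                nrow(sub), ")")
      sub$answer[seq_len(n)]
    }
  }

  audit <- list(); items <- list(); step <- 0L
  for (pid in photo_ids) {
    item <- list(photo_id = pid, tier_id = workflow$start,
                 status = "pending", history = list())
    n_tasks <- 0L
    while (item$status == "pending") {
      tier <- workflow$tiers[[item$tier_id]]
      n_tasks <- n_tasks + 1L
      ans <- get_answers(pid, tier$question_id, tier$required_raters)
      cons <- majority_vote(ans, rule = tier$rule$type,
                            threshold = tier$rule$threshold %||% (2 / 3),
                            photo_id = pid, question_id = tier$question_id)
      prev_tier <- item$tier_id
      item <- route_next(item, cons, workflow)
      step <- step + 1L
      audit[[step]] <- data.frame(
        step = step, photo_id = pid, tier_id = prev_tier,
        decision = if (is_no_consensus(cons)) "NO_CONSENSUS" else cons$decision,
        vote_fraction = cons$vote_fraction,
        outcome = if (item$status == "pending") item$tier_id else item$status,
        stringsAsFactors = FALSE)
    }
    items[[pid]] <- data.frame(photo_id = pid, status = item$status,
                               n_tasks = n_tasks, stringsAsFactors = FALSE)
  }
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(step = integer(), photo_id = character(),
               tier_id = character(), decision = character(),
               vote_fraction = numeric(), outcome = character())
  items <- do.call(rbind, c(items, list(make.row.names = FALSE)))
  structure(list(items = items, audit = audit,
                 task_counts = table(audit$tier_id)),
            class = "workflow_run")
}

#' @export
print.workflow_run <- function(x, ...) {
  tab <- table(factor(x$items$status,
                      levels = c("resolved", "escalated", "filtered_out")))
  cat(sprintf(
    "Workflow run: %d photos -> %d resolved, %d escalated, %d filtered out (%d tasks issued)\n",
    nrow(x$items), tab["resolved"], tab["escalated"], tab["filtered_out"],
    sum(x$items$n_tasks)))
  invisible(x)
}

#' Read a workflow definition from YAML
#'
#' Expected layout:
#' ```yaml
#' start: presence
#' tiers:
#'   presence:
#'     question: ad_presence
#'     required_raters: 5
#'     rule: {type: plurality}
#'     routes:
#'       - {when: absent, to: FILTER}
#'       - {when: NO_CONSENSUS, to: ESCALATE}
#'       - {when: "*", to: brand}
#' payment: {base_rate: 0.05, multiplier: 1.5}
#' ```
#'
#' @param path path to the YAML file.
#' @return list with `workflow` (a [workflow_def()]) and `payment`
#'   (base rate and multiplier, if given).
#' @export
read_workflow <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$tiers)) stop_pc("workflow file has no tiers")
  tiers <- lapply(names(y$tiers), function(id) {
    t <- y$tiers[[id]]
    task_tier(id,
              question_id = t$question %||% stop_pc("tier '", id, "' has no question"),
              required_raters = t$required_raters %||% 5,
              rule = t$rule %||% list(type = "plurality"),
              routes = lapply(t$routes, function(r) route(r$when, r$to)))
  })
  list(workflow = workflow_def(tiers, start = y$start),
       payment = y$payment)
}
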