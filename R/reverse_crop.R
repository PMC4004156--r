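#' Black out already-found regions of a photo
#'
#' The reverse-crop ("black-out") step: regions cropped in earlier
#' rounds are masked before the photo is shown to the next rater, so
#' later raters work on a simpler image and easy-to-spot items are not
#' found over and over. The mask is stored as a region list, never as
#' pixels; the masked area is the area of the union of the boxes, so
#' overlapping crops are not double counted.
#'
#' @param photo one photo: a list or one-row data frame with `photo_id`,
#'   `width_px`, `height_px`.
#' @param found data frame of crop boxes already found (may be empty).
#' @param reveal_toggle if `TRUE`, the masked regions are marked as
#'   visually recoverable — a rater may toggle them back on when an
#'   earlier crop was drawn too wide.
#' @return object of class `masked_photo`: list with `photo_id`, `mask`
#'   (the deduplicated region list), `masked_area`, `visible_area`,
#'   `revealable`.
#' @export
apply_reverse_crop <- function(photo, found, reveal_toggle = FALSE) {
  if (is.data.frame(photo)) photo <- as.list(photo[1, ])
  found <- as.data.frame(found)
  if (nrow(found) > 0) {
    validate_boxes(found, photo$width_px, photo$height_px)
    found <- unique(found[, c("x0", "y0", "x1", "y1")])
  }
  area <- rect_union_area(found)
  total <- photo$width_px * photo$height_px
  structure(list(photo_id = photo$photo_id, mask = found,
                 masked_area = area, visible_area = total - area,
                 revealable = isTRUE(reveal_toggle)),
            class = "masked_photo")
}

#' @export
print.masked_photo <- function(x, ...) {
  cat(sprintf("Masked photo %s: %d region(s), %.0f px masked%s\n",
              x$photo_id, nrow(x$mask), x$masked_area,
              if (x$revealable) " (revealable)" else ""))
  invisible(x)
}

#' Deduplicate crop discoveries across black-out rounds
#'
#' Items found in successive reverse-crop rounds are matched by IoU
#' clustering: boxes from any round that denote the same item fall into
#' one cluster. Each cluster's discovery round is the earliest round
#' containing a member; members reported in later rounds are redundant
#' finds of an already-discovered item. Items first discovered in late
#' rounds are the difficult-to-spot ones.
#'
#' @param rounds ordered list of crop data frames, one per round (each
#'   with `x0, y0, x1, y1` and optional `tag`, `rater_id`).
#' @param iou_threshold minimum IoU for two boxes to denote the same
#'   item. Default 0.5.
#' @return object of class `discovery_ledger`: list with
#'   `clusters` (cluster geometry plus `discovery_round` and
#'   `redundancy`, the number of later-round members) and
#'   `members` (one row per reported box: `round, rater_id, tag,
#'   cluster_id, credited`, where `credited` marks boxes from the
#'   cluster's discovery round).
#' @export
deduplicate_discoveries <- function(rounds, iou_threshold = 0.5) {
  if (length(rounds) == 0) stop_pc("rounds must be nonempty")
  tagged <- lapply(seq_along(rounds), function(r) {
    df <- as.data.frame(rounds[[r]])
    if (nrow(df) == 0) return(NULL)
    if (!"tag" %in% names(df)) df$tag <- "untagged"
    if (!"rater_id" %in% names(df)) df$rater_id <- NA_character_
    df$round <- r
    df[, c("x0", "y0", "x1", "y1", "tag", "rater_id", "round")]
  })
  all_boxes <- do.call(rbind, tagged)
  if (is.null(all_boxes) || nrow(all_boxes) == 0) {
    return(structure(list(
      clusters = data.frame(cluster_id = integer(), tag = character(),
                            x0 = numeric(), y0 = numeric(), x1 = numeric(),
                            y1 = numeric(), support = integer(),
                            n_boxes = integer(), discovery_round = integer(),
                            redundancy = integer()),
      members = data.frame(round = integer(), rater_id = character(),
                           tag = character(), cluster_id = integer(),
                           credited = logical())),
      class = "discovery_ledger"))
  }
  cl <- cluster_crops(all_boxes, iou_threshold)
  disc <- tapply(all_boxes$round, cl$membership, min)
  clusters <- cl$clusters
  clusters$discovery_round <- as.integer(disc[as.character(clusters$cluster_id)])
  clusters$redundancy <- vapply(clusters$cluster_id, function(k)
    sum(cl$membership == k &
          all_boxes$round > clusters$discovery_round[clusters$cluster_id == k]),
    integer(1))
  members <- data.frame(round = all_boxes$round,
                        rater_id = all_boxes$rater_id,
                        tag = all_boxes$tag,
                        cluster_id = cl$membership,
                        stringsAsFactors = FALSE)
  members$credited <- members$round ==
    clusters$discovery_round[members$cluster_id]
  structure(list(clusters = clusters, members = members),
            class = "discovery_ledger")
}

#' @export
print.discovery_ledger <- function(x, ...) {
  cat(sprintf("Discovery ledger: %d item(s) from %d reported box(es)\n",
              nrow(x$clusters), nrow(x$members)))
  if (nrow(x$clusters) > 0)
    print.data.frame(x$clusters[, c("cluster_id", "tag", "discovery_round",
                                    "n_boxes", "redundancy")],
                     row.names = FALSE)
  invisible(x)
}

#' Graded payments for reverse-crop discoveries
#'
#' Items that survive to later black-out rounds are harder to find, so
#' their discoverers earn more: a credited discovery in round r pays
#' `base_rate * multiplier^(r - 1)`, while redundant finds of an
#' already-discovered item pay the base rate only. Payments are
#' therefore never below the base rate and nondecreasing in the
#' discovery round.
#'
#' @param ledger a [deduplicate_discoveries()] result.
#' @param base_rate payment per reported box, in currency units (> 0).
#' @param multiplier geometric difficulty multiplier per round (>= 1).
#' @return data frame: `rater_id, n_finds, n_credited, payment`.
#' @examples
#' # a credited round-3 find with multiplier 2 pays 4x the base rate
#' @export
compute_payment <- function(ledger, base_rate = 0.05, multiplier = 1.5) {
  stopifnot(inherits(ledger, "discovery_ledger"))
  if (base_rate <= 0) stop_pc("base_rate must be positive")
  if (multiplier < 1) stop_pc("multiplier must be >= 1")
  m <- ledger$members
  if (nrow(m) == 0)
    return(data.frame(rater_id = character(), n_finds = integer(),
                      n_credited = integer(), payment = numeric()))
  pay <- ifelse(m$credited, base_rate * multiplier^(m$round - 1), base_rate)
  out <- aggregate(cbind(payment = pay, n_finds = 1, n_credited = m$credited),
                   by = list(rater_id = m$rater_id), FUN = sum)
  out <- out[order(out$rater_id),
             c("rater_id", "n_finds", "n_credited", "payment")]
  rownames(out) <- NULL
  out$n_finds <- as.integer(out$n_finds)
  out$n_credited <- as.integer(out$n_credited)
  out
}
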