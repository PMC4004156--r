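#' Construct and validate crop boxes
#'
#' A crop box is an axis-aligned rectangle in pixel coordinates, origin
#' at the top-left of the photo, with half-open extent
#' `[x0, x1) x [y0, y1)`. The half-open convention makes areas exact
#' integer pixel counts and lets adjacent boxes tile without overlap.
#'
#' @param x0,y0,x1,y1 numeric vectors of box edges; `x0 < x1`,
#'   `y0 < y1` elementwise.
#' @param tag category label(s) associated with the box (recycled).
#' @param rater_id optional rater identifier(s) (recycled).
#' @param width_px,height_px optional photo frame; when given, boxes must
#'   lie inside `[0, width_px] x [0, height_px]`.
#' @return data frame of class `crop_boxes` with columns
#'   `x0, y0, x1, y1, tag, rater_id`.
#' @examples
#' crop_box(0, 0, 10, 10, tag = "ad")
#' @export
crop_box <- function(x0, y0, x1, y1, tag = "untagged", rater_id = NA_character_,
                     width_px = NULL, height_px = NULL) {
  n <- max(length(x0), length(y0), length(x1), length(y1))
  df <- data.frame(x0 = rep_len(as.numeric(x0), n),
                   y0 = rep_len(as.numeric(y0), n),
                   x1 = rep_len(as.numeric(x1), n),
                   y1 = rep_len(as.numeric(y1), n),
                   tag = rep_len(as.character(tag), n),
                   rater_id = rep_len(as.character(rater_id), n),
                   stringsAsFactors = FALSE)
  validate_boxes(df, width_px, height_px)
  class(df) <- c("crop_boxes", "data.frame")
  df
}

validate_boxes <- function(df, width_px = NULL, height_px = NULL) {
  req <- c("x0", "y0", "x1", "y1")
  if (!all(req %in% names(df))) stop_pc("boxes need columns x0, y0, x1, y1")
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df[req])) stop_pc("box coordinates must not be missing")
  if (any(df$x0 >= df$x1) || any(df$y0 >= df$y1))
    stop_pc("degenerate box: need x0 < x1 and y0 < y1 (zero area not allowed)")
  if (any(df$x0 < 0) || any(df$y0 < 0))
    stop_pc("box coordinates must be nonnegative")
  if (!is.null(width_px) && any(df$x1 > width_px))
    stop_pc("box exceeds photo width")
  if (!is.null(height_px) && any(df$y1 > height_px))
    stop_pc("box exceeds photo height")
  invisible(df)
}

box_area <- function(df) (df$x1 - df$x0) * (df$y1 - df$y0)

#' Intersection-over-union of two crop boxes
#'
#' Two raters asked to crop the same advertisement draw very similar but
#' almost never pixel-identical boxes; IoU (Jaccard overlap of the two
#' rectangles) is the agreement metric used to decide whether two boxes
#' denote the same item.
#'
#' @param a,b single boxes: either one-row data frames with columns
#'   `x0, y0, x1, y1` or numeric vectors `c(x0, y0, x1, y1)`.
#' @return numeric in \[0, 1\]; 1 iff the boxes are identical, 0 iff
#'   disjoint.
#' @examples
#' crop_iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 0.5
#' @export
crop_iou <- function(a, b) {
  a <- as_box_vec(a); b <- as_box_vec(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (area_a + area_b - inter)
}

as_box_vec <- function(b) {
  if (is.data.frame(b)) {
    stopifnot(nrow(b) == 1)
    b <- c(b$x0, b$y0, b$x1, b$y1)
  }
  b <- as.numeric(b)
  if (length(b) != 4 || b[1] >= b[3] || b[2] >= b[4])
    stop_pc("a box is c(x0, y0, x1, y1) with x0 < x1, y0 < y1")
  b
}

pairwise_iou <- function(df) {
  n <- nrow(df)
  m <- diag(1, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <-
        crop_iou(c(df$x0[i], df$y0[i], df$x1[i], df$y1[i]),
                 c(df$x0[j], df$y0[j], df$x1[j], df$y1[j]))
    }
  }
  m
}

#' Cluster near-duplicate crop boxes across raters
#'
#' Single-linkage clustering on the graph connecting same-tag boxes with
#' IoU at or above `iou_threshold`: connected components of that graph
#' are the distinct items the crowd found. Each cluster reports a
#' representative box (coordinate-wise median of its members) and its
#' support, the number of distinct raters contributing a member.
#'
#' @param boxes a `crop_boxes` data frame (or any data frame with
#'   `x0, y0, x1, y1` and optional `tag`, `rater_id` columns).
#' @param iou_threshold minimum IoU to link two boxes, in (0, 1\].
#'   Default 0.5, the usual detection-overlap convention.
#' @return list with `clusters` (data frame: `cluster_id`, `tag`,
#'   representative `x0, y0, x1, y1`, `support`, `n_boxes`) and
#'   `membership` (integer cluster id per input row).
#' @export
cluster_crops <- function(boxes, iou_threshold = 0.5) {
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1)
    stop_pc("iou_threshold must be in (0, 1]")
  boxes <- as.data.frame(boxes)
  if (!"tag" %in% names(boxes)) boxes$tag <- "untagged"
  if (!"rater_id" %in% names(boxes)) boxes$rater_id <- NA_character_
  validate_boxes(boxes)
  n <- nrow(boxes)
  if (n == 0) {
    return(list(clusters = data.frame(cluster_id = integer(), tag = character(),
                                      x0 = numeric(), y0 = numeric(),
                                      x1 = numeric(), y1 = numeric(),
                                      support = integer(), n_boxes = integer()),
                membership = integer()))
  }
  iou <- pairwise_iou(boxes)
  same_tag <- outer(boxes$tag, boxes$tag, "==")
  adj <- (iou >= iou_threshold) & same_tag
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # renumber clusters in order of first appearance, for determinism
  comp <- match(comp, unique(comp))

  clusters <- do.call(rbind, lapply(seq_len(max(comp)), function(k) {
    mem <- boxes[comp == k, , drop = FALSE]
    raters <- unique(mem$rater_id[!is.na(mem$rater_id)])
    support <- if (length(raters) > 0) length(raters) else nrow(mem)
    data.frame(cluster_id = k, tag = mem$tag[1],
               x0 = stats::median(mem$x0), y0 = stats::median(mem$y0),
               x1 = stats::median(mem$x1), y1 = stats::median(mem$y1),
               support = support, n_boxes = nrow(mem),
               stringsAsFactors = FALSE)
  }))
  list(clusters = clusters, membership = comp)
}

#' Area of the union of a set of rectangles
#'
#' Exact union area by sweeping vertical strips between distinct x
#' coordinates and merging y intervals within each strip. Overlapping
#' boxes are counted once (inclusion-exclusion semantics).
#'
#' @param boxes data frame with `x0, y0, x1, y1`.
#' @return numeric area in square pixels.
#' @export
rect_union_area <- function(boxes) {
  boxes <- as.data.frame(boxes)
  if (nrow(boxes) == 0) return(0)
  validate_boxes(boxes)
  xs <- sort(unique(c(boxes$x0, boxes$x1)))
  total <- 0
  for (i in seq_len(length(xs) - 1)) {
    xa <- xs[i]; xb <- xs[i + 1]
    hit <- boxes$x0 <= xa & boxes$x1 >= xb
    if (!any(hit)) next
    ys <- boxes[hit, c("y0", "y1"), drop = FALSE]
    ys <- ys[order(ys$y0, ys$y1), , drop = FALSE]
    covered <- 0; cur_lo <- ys$y0[1]; cur_hi <- ys$y1[1]
    if (nrow(ys) > 1) {
      for (j in 2:nrow(ys)) {
        if (ys$y0[j] > cur_hi) {
          covered <- covered + (cur_hi - cur_lo)
          cur_lo <- ys$y0[j]; cur_hi <- ys$y1[j]
        } else cur_hi <- max(cur_hi, ys$y1[j])
      }
    }
    covered <- covered + (cur_hi - cur_lo)
    total <- total + covered * (xb - xa)
  }
  total
}
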