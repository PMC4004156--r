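# Independent brute-force oracles used across the suite. These stay
# deliberately naive: they enumerate rather than share code with the
# implementation they check.

# Mann-Whitney AUC by explicit pairwise comparison of every
# positive-negative score pair, ties counted half.
bf_auc <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Connected components of the same-tag IoU graph by breadth-first
# search over an explicit adjacency matrix.
bf_components <- function(boxes, threshold) {
  n <- nrow(boxes)
  iou_pair <- function(i, j) {
    ix <- max(0, min(boxes$x1[i], boxes$x1[j]) - max(boxes$x0[i], boxes$x0[j]))
    iy <- max(0, min(boxes$y1[i], boxes$y1[j]) - max(boxes$y0[i], boxes$y0[j]))
    inter <- ix * iy
    ai <- (boxes$x1[i] - boxes$x0[i]) * (boxes$y1[i] - boxes$y0[i])
    aj <- (boxes$x1[j] - boxes$x0[j]) * (boxes$y1[j] - boxes$y0[j])
    inter / (ai + aj - inter)
  }
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- boxes$tag[i] == boxes$tag[j] &&
        iou_pair(i, j) >= threshold
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# random valid boxes inside a frame
rand_boxes <- function(n, frame = 100, tags = "t") {
  x0 <- runif(n, 0, frame - 2); y0 <- runif(n, 0, frame - 2)
  data.frame(x0 = x0, y0 = y0,
             x1 = x0 + runif(n, 1, frame - x0),
             y1 = y0 + runif(n, 1, frame - y0),
             tag = sample(tags, n, replace = TRUE),
             rater_id = sprintf("r%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# hand-assembled crowd_size_curve for the scan operations
make_curve <- function(k, mean_auc, ci_lo = mean_auc - 0.05,
                       ci_hi = pmin(1, mean_auc + 0.05),
                       sd_auc = rep(0.02, length(k))) {
  structure(data.frame(k = k, mean_auc = mean_auc, ci_lo = ci_lo,
                       ci_hi = ci_hi, sd_auc = sd_auc,
                       n_samples = 50),
            class = c("crowd_size_curve", "data.frame"))
}

# small complete binary rating table built from an explicit matrix
ratings_from_matrix <- function(m, question = "ad_presence") {
  data.frame(
    photo_id = rep(rownames(m), times = ncol(m)),
    rater_id = rep(colnames(m), each = nrow(m)),
    task_id = "t", question_id = question, answer_type = "binary",
    answer = ifelse(as.vector(m), "present", "absent"),
    timestamp = NA_character_, stringsAsFactors = FALSE)
}
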