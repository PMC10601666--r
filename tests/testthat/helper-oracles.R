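# Independent oracles and small fixture builders shared across tests. Each
# oracle deliberately takes a different route than the implementation it
# checks.

# exact two-sided rank-sum p by full combn() enumeration over mid-ranks
rank_sum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  cmb <- utils::combn(n, n1)
  W <- colSums(matrix(r[cmb], nrow = n1))
  eps <- 1e-9
  p_le <- mean(W <= w + eps)
  p_ge <- mean(W >= w - eps)
  min(1, 2 * min(p_le, p_ge))
}

# O(m^2) BH step-up oracle: scan every threshold directly
bh_oracle <- function(p, level = 0.05) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))))
  }
  k <- 0
  for (j in seq_len(m)) if (p[o[j]] <= j * level / m) k <- j
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  list(q_values = q, rejected = rejected)
}

# brute-force two-sided binomial sign test by direct pmf summation
sign_oracle <- function(k, n) {
  pmf <- vapply(0:n, function(i) choose(n, i) * 0.5^n, numeric(1))
  min(1, 2 * min(sum(pmf[seq_len(k + 1)]), sum(pmf[(k + 1):(n + 1)])))
}

# per-id ancestor walk for tier aggregation (independent of aggregate_counts)
aggregate_oracle <- function(counts, atlas, level_tag) {
  nodes <- atlas$nodes
  root <- nodes$id[is.na(nodes$parent_id)]
  out <- list()
  for (rid in names(counts)) {
    cur <- as.integer(rid)
    repeat {
      tag <- nodes$level_tag[nodes$id == cur]
      if (tag == level_tag) break
      p <- nodes$parent_id[nodes$id == cur]
      if (is.na(p)) { cur <- root; break }
      cur <- p
    }
    key <- as.character(cur)
    out[[key]] <- (out[[key]] %||% 0) + counts[[rid]]
  }
  unlist(out)[order(as.integer(names(unlist(out))))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform placement with minimum spacing, no atlas constraint
place_free <- function(n, h, w, spacing, margin = 10) {
  pts <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(pts) < n) {
    guard <- guard + 1
    if (guard > 50000) stop("place_free: cannot satisfy spacing")
    p <- c(stats::runif(1, margin, w - margin), stats::runif(1, margin, h - margin))
    if (!nrow(pts) ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= spacing) {
      pts <- rbind(pts, p)
    }
  }
  pts
}

# tiny 6-node hierarchy used across atlas/quantify tests:
# root(10,meta) -> STR(11,meta) -> MEA(1,leaf), CEA(2,leaf)
#               -> ORB(12,summary) -> ORBl(3,leaf)
tiny_nodes <- function() {
  data.frame(
    id = c(10L, 11L, 12L, 1L, 2L, 3L),
    acronym = c("BRAIN", "STR", "ORB", "MEA", "CEA", "ORBl"),
    name = c("root", "striatum-ish", "orbital", "medial amygdala",
             "central amygdala", "orbital lateral"),
    parent_id = c(NA, 10L, 10L, 11L, 11L, 12L),
    level_tag = c("meta", "meta", "summary", "leaf", "leaf", "leaf")
  )
}

tiny_atlas <- function(n_slices = 1) {
  mask <- matrix(0L, 10, 10)
  mask[2:9, 2:5] <- 1L
  mask[2:9, 6:9] <- 2L
  mask[1, 5:6] <- 3L
  slices <- lapply(seq_len(n_slices), function(i) {
    atlas_slice(mask, ap_mm = 1 - (i - 1), pixel_size_um = 10, midline_x = 5)
  })
  region_atlas(tiny_nodes(), slices)
}

make_sample <- function(id = "S1", sex = "male", starters, presynaptic,
                        target = "amygdala", side = "left") {
  hemisphere_sample(id, sex, target, side, starters, presynaptic)
}
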