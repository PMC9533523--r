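# Shared fixture builders and independent oracles.

# one-hot probability map from a label matrix (labels by class name)
pmap_from_labels <- function(label_names, meta = slide_meta("fix", 224L, 112L)) {
  labs <- matrix(match(label_names, TISSUE_CLASSES), nrow(label_names), ncol(label_names))
  grid <- array(0, c(nrow(labs), ncol(labs), 9L))
  for (k in 1:9) grid[, , k] <- (labs == k) * 1
  probability_map(grid, meta)
}

label_matrix <- function(names_vec, nrow, ncol) {
  matrix(names_vec, nrow, ncol)
}

# set P(LYM) on chosen cells of a one-hot STR map, remainder on STR
set_lym <- function(pmap, cells, p_lym) {
  lym <- match("LYM", TISSUE_CLASSES); str <- match("STR", TISSUE_CLASSES)
  for (i in seq_along(cells)) {
    rc <- cells[[i]]
    pmap$grid[rc[1], rc[2], ] <- 0
    pmap$grid[rc[1], rc[2], lym] <- p_lym[i]
    pmap$grid[rc[1], rc[2], str] <- 1 - p_lym[i]
  }
  probability_map(pmap$grid, pmap$meta)
}

# brute-force Harrell C: enumerate all pairs, ties in risk count 0.5
c_index_oracle <- function(risk, times, events) {
  n <- length(risk); num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    # usable pair: i has the earlier observed event
    if (events[i] == 1 && times[i] < times[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# brute-force 2-group log-rank: observed minus expected over event-time risk sets
logrank_oracle_2g <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  stopifnot(max(g) == 2L)
  ev_times <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    d <- sum(events == 1 & times == t)
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1L)
    d1 <- sum(events == 1 & times == t & g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# product-limit estimator from first principles
km_oracle_at <- function(times, events, t) {
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  for (tt in ev_times[ev_times <= t]) {
    n <- sum(times >= tt)
    d <- sum(times == tt & events == 1)
    s <- s * (1 - d / n)
  }
  s
}

# draw a brown disk on a white RGB image (0-based center coords);
# default color has brown-likeness min(R, G) - B = 0.35, above the 0.3 default
draw_disk <- function(img, cx, cy, radius, color = c(0.55, 0.45, 0.1)) {
  H <- dim(img)[1]; W <- dim(img)[2]
  for (r in max(1, cy + 1 - radius):min(H, cy + 1 + radius))
    for (c in max(1, cx + 1 - radius):min(W, cx + 1 + radius))
      if ((r - 1 - cy)^2 + (c - 1 - cx)^2 <= radius^2)
        img[r, c, ] <- color
  img
}
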