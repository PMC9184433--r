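# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, no shared code with R/) so they
# cross-check the package implementations rather than restate them.

# All integer compositions (p3, p4, p5) summing to 100.
integer_compositions <- function(step = 1) {
  g <- expand.grid(p3 = seq(0, 100, step), p4 = seq(0, 100, step))
  g <- g[g$p3 + g$p4 <= 100, ]
  g$p5 <- 100 - g$p3 - g$p4
  rownames(g) <- NULL
  g
}

# Scalar Gleason oracle: primary = most extensive pattern (ties to the
# higher grade), secondary = highest-grade other pattern with >= 5%,
# else secondary = primary; tertiary 5 when 0 < p5 < 5 and pattern 5 is
# not a score component.
oracle_gleason <- function(p3, p4, p5) {
  pct <- c("3" = p3, "4" = p4, "5" = p5)
  prim <- max(as.integer(names(pct)[pct == max(pct)]))
  others <- setdiff(c(3L, 4L, 5L), prim)
  elig <- others[pct[as.character(others)] >= 5]
  sec <- if (length(elig)) max(elig) else prim
  gs <- prim + sec
  gg <- if (gs <= 6) 1L else if (gs == 7 && prim == 3) 2L
        else if (gs == 7) 3L else if (gs == 8) 4L else 5L
  list(primary = prim, secondary = sec, gleason_score = gs,
       grade_group = gg,
       tertiary5 = p5 > 0 && p5 < 5 && prim != 5 && sec != 5)
}

# O(n^2) pair-enumeration oracle for Harrell's c.
oracle_harrell <- function(time, event, score) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (event[i] && time[i] < time[j]) ||
      (event[i] && !event[j] && time[i] == time[j])
    if (!comparable) next
    den <- den + 1
    if (score[i] > score[j]) num <- num + 1
    else if (score[i] == score[j]) num <- num + 0.5
  }
  list(c = num / den, n_comparable_pairs = den)
}

# Random valid compositions (continuous, one-decimal granularity).
random_compositions <- function(n) {
  raw <- matrix(stats::rexp(3 * n), ncol = 3)
  pm <- raw / rowSums(raw) * 100
  pm <- round(pm, 1)
  resid <- 100 - rowSums(pm)
  big <- max.col(pm)
  pm[cbind(seq_len(n), big)] <- pm[cbind(seq_len(n), big)] + resid
  data.frame(p3 = pm[, 1], p4 = pm[, 2], p5 = pm[, 3])
}
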