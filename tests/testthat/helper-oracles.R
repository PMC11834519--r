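# Independent oracles used to check the LP-based DEA solver.

# Geometric vertex-enumeration oracle for the 1-input/1-output VRS
# slack-maximisation problem. The optimal objective is
#   max over attainable (P, Q) of (x_l - P) + (Q - y_l)
# subject to P <= x_l, Q >= y_l, where (P, Q) ranges over the convex hull
# of the observed points. Q at fixed P is bounded by the hull's upper
# boundary H(P), enumerated by brute force over single points and pairs;
# candidate P values are the data abscissae, x_l, every pair-line crossing
# of the level y_l, and every pair-line intersection. No LP involved.
oracle_sbm_1x1 <- function(x, y, l) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  hull_Q <- function(P) {
    best <- -Inf
    for (i in seq_len(n)) if (abs(x[i] - P) < 1e-12) best <- max(best, y[i])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (x[i] < P && P < x[j]) {
        t <- (P - x[i]) / (x[j] - x[i])
        best <- max(best, y[i] + t * (y[j] - y[i]))
      }
    }
    best
  }
  cand <- c(x[x <= x[l] + 1e-12], x[l])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (x[i] < x[j] && y[j] != y[i]) {
      # crossing of segment (i, j) with the horizontal level y_l
      P <- x[i] + (y[l] - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
      if (P >= x[i] - 1e-12 && P <= min(x[j], x[l]) + 1e-12) cand <- c(cand, P)
      # intersections with every other segment (kinks of the boundary)
      for (a in seq_len(n)) for (b in seq_len(n)) {
        if (x[a] < x[b] && (a != i || b != j)) {
          s1 <- (y[j] - y[i]) / (x[j] - x[i])
          s2 <- (y[b] - y[a]) / (x[b] - x[a])
          if (abs(s1 - s2) > 1e-12) {
            P <- ((y[a] - s2 * x[a]) - (y[i] - s1 * x[i])) / (s1 - s2)
            if (P >= max(x[i], x[a]) - 1e-12 &&
                P <= min(x[j], x[b], x[l]) + 1e-12) cand <- c(cand, P)
          }
        }
      }
    }
  }
  best <- 0  # the DMU itself is always attainable
  for (P in unique(cand)) {
    if (P > x[l] + 1e-12) next
    Q <- hull_Q(P)
    if (Q >= y[l] - 1e-12)
      best <- max(best, (x[l] - P) + (Q - y[l]))
  }
  best
}

# strict-dominance oracle: does unit a strictly dominate unit b?
dominates <- function(xa, ya, xb, yb) {
  all(xa <= xb) && all(ya >= yb) && (any(xa < xb) || any(ya > yb))
}

# small random panel with m inputs / p outputs, entries in [lo, hi]
random_panel <- function(n, m = 1, p = 1, lo = 1, hi = 10,
                         perspective = "custom") {
  X <- matrix(round(runif(n * m, lo, hi), 3), n, m)
  Y <- matrix(round(runif(n * p, lo, hi), 3), n, p)
  sc <- new_test_schema(m, p)
  performance_panel(perspective, sprintf("D%02d", seq_len(n)), X, Y, sc)
}

new_test_schema <- function(m, p) {
  data.frame(
    code = c(sprintf("IN%d", seq_len(m)), sprintf("OUT%d", seq_len(p))),
    name = c(sprintf("input %d", seq_len(m)), sprintf("output %d", seq_len(p))),
    dimension = rep("Economy", m + p),
    role = c(rep("input", m), rep("output", p)),
    scale = rep("count", m + p),
    stringsAsFactors = FALSE)
}

# 1-input/1-output panel from plain vectors
panel_1x1 <- function(x, y) {
  performance_panel("custom", sprintf("D%02d", seq_along(x)),
                    matrix(x, ncol = 1), matrix(y, ncol = 1),
                    new_test_schema(1, 1))
}

# panel with one planted strictly dominated DMU appended; returns the panel
# and the index of the planted unit
plant_dominated <- function(n, m, p) {
  pan <- random_panel(n, m, p)
  parent <- sample.int(n, 1)
  x_bad <- pan$X[parent, ] * runif(m, 1.05, 1.5)
  y_bad <- pan$Y[parent, ] * runif(p, 0.5, 0.95)
  X <- rbind(pan$X, x_bad)
  Y <- rbind(pan$Y, y_bad)
  panel <- performance_panel("custom", sprintf("D%02d", seq_len(n + 1)),
                             X, Y, pan$columns)
  list(panel = panel, bad = n + 1, parent = parent)
}
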