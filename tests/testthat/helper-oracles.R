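# Independent oracles and small fixture builders shared across tests.

# Brute-force nearest-HRSC distances: explicit loop over cells and all CD30+
# reference cells.
oracle_nearest_distance <- function(map) {
  hrsc <- which(map$cells$CD30)
  vapply(seq_len(n_cells(map)), function(i) {
    if (map$cells$CD30[i]) return(0)
    best <- Inf
    for (j in hrsc) {
      d <- sqrt((map$cells$x[i] - map$cells$x[j])^2 +
                (map$cells$y[i] - map$cells$y[j])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

# Two-sided Fisher p by full enumeration with an lfactorial-based pmf
# (independent of the package's lchoose formulation).
oracle_fisher_p <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ])
  c1 <- sum(t[, 1]); c2 <- sum(t[, 2]); n <- sum(t)
  logpmf <- function(a) {
    b <- r1 - a; c_ <- c1 - a; d <- r2 - c_
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(c_) -
      lfactorial(d)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(support, logpmf, numeric(1))
  p_obs <- exp(logpmf(t[1, 1]))
  sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)])
}

# Textbook paired t on a vector of differences.
oracle_paired_t <- function(diffs) {
  n <- length(diffs)
  t <- mean(diffs) / (stats::sd(diffs) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Random 2x2 table with total n and no zero margin.
random_2x2 <- function(n) {
  repeat {
    t <- matrix(stats::rmultinom(1, n, stats::runif(4, 0.05, 1)), 2)
    if (all(rowSums(t) > 0) && all(colSums(t) > 0)) return(t)
  }
}

# Random cell map: n cells uniform in a square field, n_hrsc of them CD30+,
# other markers assigned at random.
random_cell_map <- function(n, n_hrsc, field = 500, case_id = "rnd") {
  stopifnot(n_hrsc >= 1, n >= n_hrsc)
  cd30 <- c(rep(TRUE, n_hrsc), rep(FALSE, n - n_hrsc))
  cells <- data.frame(
    x = stats::runif(n, 0, field), y = stats::runif(n, 0, field),
    CD30 = cd30,
    CD8 = !cd30 & stats::runif(n) < 0.4,
    CD3 = !cd30 & stats::runif(n) < 0.6,
    CD68 = !cd30 & stats::runif(n) < 0.2,
    LAG3 = !cd30 & stats::runif(n) < 0.2,
    FoxP3 = !cd30 & stats::runif(n) < 0.1,
    PD1 = !cd30 & stats::runif(n) < 0.15,
    TIM3 = !cd30 & stats::runif(n) < 0.05)
  cell_map(cells, case_id = case_id)
}

# Balanced two-group annotation for DE tests.
balanced_annotation <- function(n_per_group, ebv = "neg") {
  sample_annotation(sprintf("s%03d", seq_len(2 * n_per_group)),
                    hla_i = rep(c("pos", "neg"), each = n_per_group),
                    ebv = ebv)
}

# Centered expression matrix from a plain matrix of log2-scale values.
centered_matrix <- function(values) {
  expression_matrix(sweep(values, 2, colMeans(values)), state = "centered")
}
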