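# Independent oracles and small fixtures used across the suite.

# One-component NIPALS PLS1, written directly from the textbook recipe and
# kept independent of the package's OPLS path.
pls1_oracle <- function(X, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  t_ <- drop(X %*% w)
  list(w = w, t = t_,
       p = drop(crossprod(X, t_)) / sum(t_^2),
       c = sum(yc * t_) / sum(t_^2))
}

# Tie-aware Mann-Whitney AUC: P(pos > neg) + 0.5 P(pos == neg) by explicit
# pair counting.
auc_mw_oracle <- function(response, labels, positive) {
  pos <- response[labels == positive]
  neg <- response[labels != positive]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Pooled-variance two-sample t statistic and two-sided p, from the closed
# form (no call into stats::t.test).
t_closed_form <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t_ <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t_, p = 2 * stats::pt(-abs(t_), na + nb - 2))
}

# Mean silhouette width on a small score matrix, hand-rolled (euclidean).
silhouette_mean <- function(points, groups) {
  d <- as.matrix(stats::dist(points))
  groups <- as.character(groups)
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# A reduced study design used by the module tests: same structure as the
# default (4 years, paired fields, 2 blocks), scaled down for speed.
small_config <- function(...) {
  synthetic_config(n_variables = 250L, n_blocks = 2L,
                   replicates_per_field = 4L, ...)
}

# Shared small dataset (computed once per test run).
small_ds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(small_config(seed = 11))
    cache
  }
})

# Brute-force grid assignment: scan for the half-open cell that contains x,
# with edges computed as lo + i * delta.
grid_scan_oracle <- function(x, lo, hi, delta) {
  n_cells <- ceiling((hi - lo) / delta)
  for (i in 0:(n_cells - 1)) {
    if (x >= lo + i * delta && x < lo + (i + 1) * delta) return(i)
  }
  NA_integer_
}
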