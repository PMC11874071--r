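# Independent oracles, written as plain step-by-step R so they share no code
# path with the package implementations they check.

# O(N^2) sample-entropy template counting, straight from the definition.
sampen_oracle <- function(x, m = 1L, r_frac = 0.15) {
  s <- sd(x)
  if (s == 0) return(0)
  r <- r_frac * s
  nt <- length(x) - m
  a <- 0L
  b <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- 0
      for (k in 0:(m - 1L)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r) {
        b <- b + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) a <- a + 1L
      }
    }
  }
  if (a == 0L || b == 0L) return(NA_real_)
  -log(a / b)
}

# Standardized AR(1) series generator used across the suite.
gen_ar <- function(n, phi, burn = 50L) {
  x <- as.numeric(stats::filter(rnorm(n + burn), phi, method = "recursive"))
  x <- x[-seq_len(burn)]
  x / sd(x)
}

# Rosner's generalized ESD, computed as a literal table of R_i and lambda_i.
gesd_oracle <- function(x, max_k, alpha = 0.05) {
  n <- length(x)
  work <- x
  idx <- seq_len(n)
  tab <- data.frame(step = integer(0), removed = integer(0),
                    R = numeric(0), lambda = numeric(0))
  for (step in seq_len(max_k)) {
    if (sd(work) == 0 || !is.finite(sd(work))) break
    z <- abs(work - mean(work)) / sd(work)
    pos <- which.max(z)
    ni <- length(work)
    pcrit <- 1 - alpha / (2 * ni)
    tcrit <- qt(pcrit, ni - 2)
    lam <- (ni - 1) * tcrit / sqrt((ni - 2 + tcrit^2) * ni)
    tab <- rbind(tab, data.frame(step = step, removed = idx[pos],
                                 R = z[pos], lambda = lam))
    work <- work[-pos]
    idx <- idx[-pos]
  }
  hits <- which(tab$R > tab$lambda)
  if (length(hits) == 0) return(integer(0))
  tab$removed[seq_len(max(hits))]
}

# Brute-force complete-linkage agglomeration; returns the partition after
# every merge (as a list of label vectors) and the merge heights.
complete_linkage_oracle <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(dm[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    heights <- c(heights, best_h)
    lab <- integer(n)
    for (g in seq_along(clusters)) lab[clusters[[g]]] <- g
    partitions[[length(partitions) + 1L]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Canonical signature of a set partition (label-invariant).
partition_signature <- function(labels) {
  paste(match(labels, unique(labels)), collapse = ",")
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(sum(tab))
  expected <- sum_i * sum_j / total
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# OLS through the normal equations.
ols_oracle <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Closed-form large-N limit of SampEn(m = 1, r_frac) for i.i.d. Gaussian
# data: -log(2 * Phi(r_frac / sqrt(2)) - 1).
gaussian_sampen_limit <- function(r_frac = 0.15) {
  -log(2 * pnorm(r_frac / sqrt(2)) - 1)
}
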