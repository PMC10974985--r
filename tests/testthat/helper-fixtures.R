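# Shared fixtures and independent oracles for the test suite.

# small deterministic concentration matrix
tiny_conc <- function() {
  concentration_matrix(
    matrix(c(10, 30, 20, 40), nrow = 2,
           dimnames = list(c("S1", "S2"), c("Pb", "Zn")))
  )
}

tiny_background <- function() c(Pb = 5, Zn = 10)

# TRUE when two label vectors describe the same partition (bijective
# relabelling exists)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  t <- table(a, b)
  all(rowSums(t > 0) == 1) && all(colSums(t > 0) == 1)
}

# Exhaustive Ward clustering oracle: at each step evaluate every pair merge
# by its increase in total within-cluster sum of squares and take the
# minimum. Heights follow the Ward distance convention sqrt(2 * deltaSS).
# Returns heights and the partition (as labels) after each merge.
ward_oracle <- function(x) {
  groups <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  while (length(groups) > 1L) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i >= j) next
        A <- groups[[i]]; B <- groups[[j]]
        cA <- colMeans(x[A, , drop = FALSE])
        cB <- colMeans(x[B, , drop = FALSE])
        cost <- length(A) * length(B) / (length(A) + length(B)) * sum((cA - cB)^2)
        if (cost < best_cost) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, sqrt(2 * best_cost))
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
    labels <- integer(nrow(x))
    for (g in seq_along(groups)) labels[groups[[g]]] <- g
    partitions[[length(partitions) + 1L]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# three well-separated planted gaussian blobs in 2-D
planted_blobs <- function(n_per = 10, sep = 20, sd = 0.5, seed = 42) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep), ncol = 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(g) {
    cbind(rnorm(n_per, centers[g, 1], sd), rnorm(n_per, centers[g, 2], sd))
  }))
  list(x = x, labels = rep(1:3, each = n_per))
}
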