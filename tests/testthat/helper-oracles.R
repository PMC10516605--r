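# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the Weibull oracle is a profile-likelihood grid
# search (no Newton steps) and the alignment oracle enumerates every optimal
# alignment by exhaustive backtracking.

# Grid-search Weibull MLE: profile log-likelihood over the shape only (the
# scale MLE is closed-form given the shape), maximised on a coarse log grid
# and refined twice around the maximum.
grid_mle_weibull <- function(x, k_range = c(0.05, 60), n_grid = 400) {
  lx <- sum(log(x))
  n <- length(x)
  prof <- function(k) {
    lam <- (mean(x^k))^(1 / k)
    n * log(k) - n * k * log(lam) + (k - 1) * lx - sum((x / lam)^k)
  }
  grid <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_grid))
  for (round in 1:3) {
    ll <- vapply(grid, prof, 0)
    i <- which.max(ll)
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, length(grid))]
    best <- grid[i]
    grid <- seq(lo, hi, length.out = n_grid)
  }
  k <- best
  c(shape = k, scale = (mean(x^k))^(1 / k))
}

# Exhaustive enumeration of all optimal global alignments under unit
# mismatch/gap costs; returns one run-collapsed edit script per optimal
# alignment (same op conventions as align_to_reference, without
# left-normalisation).
enumerate_optimal_alignments <- function(read, ref) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a)
  m <- length(b)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in 1:n) for (j in 1:m) {
    D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]),
                           D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  }
  scripts <- list()
  walk <- function(i, j, cols) {
    if (i == 0 && j == 0) {
      scripts[[length(scripts) + 1L]] <<- rev(cols)
      return(invisible())
    }
    if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + (a[i] != b[j]))
      walk(i - 1, j - 1, c(cols, list(c(a[i], b[j]))))
    if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1L)
      walk(i - 1, j, c(cols, list(c(a[i], "-"))))
    if (j > 0 && D[i + 1, j + 1] == D[i + 1, j] + 1L)
      walk(i, j - 1, c(cols, list(c("-", b[j]))))
  }
  walk(n, m, list())
  lapply(scripts, function(cols) {
    p <- vapply(cols, `[`, "", 1)
    s <- vapply(cols, `[`, "", 2)
    ops <- list()
    refpos <- 0L
    k <- 1L
    while (k <= length(p)) {
      if (s[k] == "-") {
        start <- k
        while (k <= length(p) && s[k] == "-") k <- k + 1L
        ops[[length(ops) + 1L]] <- list(type = "ins", pos = refpos + 1L,
                                        ref = "",
                                        alt = paste(p[start:(k - 1L)],
                                                    collapse = ""))
      } else if (p[k] == "-") {
        start_ref <- refpos + 1L
        del <- character(0)
        while (k <= length(p) && p[k] == "-") {
          refpos <- refpos + 1L
          del <- c(del, s[k])
          k <- k + 1L
        }
        ops[[length(ops) + 1L]] <- list(type = "del", pos = start_ref,
                                        ref = paste(del, collapse = ""),
                                        alt = "")
      } else {
        refpos <- refpos + 1L
        if (p[k] != s[k])
          ops[[length(ops) + 1L]] <- list(type = "sub", pos = refpos,
                                          ref = s[k], alt = p[k])
        k <- k + 1L
      }
    }
    ops
  })
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
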