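# Independent oracles. These reimplement, by the most direct textbook
# route available, quantities the package computes by other means; they
# must stay independent of the code paths they check.

# 2x2 chi-squared via the four-cell shortcut formula:
# X^2 = N (|ad - bc| - c0)^2 / ((a+b)(c+d)(a+c)(b+d)), c0 = N/2 for Yates
oracle_chisq_2x2 <- function(a, b, c, d, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Pearson correlation from the raw covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# O(n^3) average-linkage agglomeration tracking every original pairwise
# distance explicitly; returns the sorted merge heights
oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq.int(i + 1L, length(groups))) {
        dd <- mean(d[groups[[i]], groups[[j]]])
        if (dd < bestd) {
          bestd <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bestd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

# Fitting alignment by full dynamic programming: the shorter sequence is
# aligned globally against any window of the longer (free end gaps on the
# longer only). match +1, mismatch -1, gap -2. Returns score, matches,
# aligned columns from the traceback.
oracle_fit_align <- function(shorter, longer) {
  p <- strsplit(shorter, "")[[1]]
  s <- strsplit(longer, "")[[1]]
  np <- length(p)
  ns <- length(s)
  GAP <- -2
  sc <- matrix(-Inf, np + 1L, ns + 1L)
  sc[1, ] <- 0                        # free leading gap in the subject
  sc[, 1] <- GAP * (0:np)
  for (i in seq_len(np)) {
    sub <- ifelse(p[i] == s, 1, -1)
    for (j in seq_len(ns)) {
      sc[i + 1L, j + 1L] <- max(sc[i, j] + sub[j],
                                sc[i, j + 1L] + GAP,
                                sc[i + 1L, j] + GAP)
    }
  }
  jend <- which.max(sc[np + 1L, ])
  score <- sc[np + 1L, jend]
  # traceback, preferring diagonal moves on ties
  i <- np + 1L
  j <- jend
  matches <- 0L
  cols <- 0L
  while (i > 1L) {
    diag_ok <- j > 1L &&
      sc[i, j] == sc[i - 1L, j - 1L] + ifelse(p[i - 1L] == s[j - 1L], 1, -1)
    if (diag_ok) {
      matches <- matches + (p[i - 1L] == s[j - 1L])
      cols <- cols + 1L
      i <- i - 1L
      j <- j - 1L
    } else if (sc[i, j] == sc[i - 1L, j] + GAP) {
      cols <- cols + 1L
      i <- i - 1L
    } else {
      cols <- cols + 1L
      j <- j - 1L
    }
  }
  list(score = score, matches = matches, cols = cols,
       identity = matches / cols, coverage = cols / np)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions of a sequence with a different base
substitute_bases <- function(seq, k) {
  b <- strsplit(seq, "")[[1]]
  pos <- sample(length(b), k)
  for (i in pos) {
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  }
  paste(b, collapse = "")
}
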