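# Independent brute-force oracles used to pin down the optimised
# implementations. These are deliberately naive re-implementations from
# the definitions and share no code with the package internals.

# LZ76 exhaustive-history parsing straight from the definition: a phrase
# grows while it is a substring of everything before its last character.
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  h <- 1
  c <- 0
  while (h <= n) {
    i <- h
    repeat {
      if (i > n) break
      phrase <- substr(s, h, i)
      if (grepl(phrase, substr(s, 1, i - 1), fixed = TRUE)) {
        i <- i + 1
      } else {
        break
      }
    }
    c <- c + 1
    h <- min(i, n) + 1
  }
  c
}

# Direct O(n^2) sample-entropy template counting.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Direct CTM enumeration.
ctm_oracle <- function(x, rho) {
  hits <- 0
  total <- 0
  for (i in seq_len(length(x) - 2)) {
    d1 <- x[i + 1] - x[i]
    d2 <- x[i + 2] - x[i + 1]
    total <- total + 1
    if (sqrt(d1^2 + d2^2) < rho) hits <- hits + 1
  }
  hits / total
}

# Plug-in symmetrical uncertainty from explicit probability sums.
su_oracle <- function(x, y) {
  px <- table(x) / length(x)
  py <- table(y) / length(y)
  pxy <- table(x, y) / length(x)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  hx <- h(px)
  hy <- h(py)
  if (hx + hy == 0) return(0)
  2 * (hx + hy - h(pxy)) / (hx + hy)
}

# FCBF from its definition: rank by relevance, walk the ranking and drop
# any feature predominated by an already-kept one.
fcbf_oracle <- function(tab, y, delta = 0) {
  su <- vapply(tab, su_oracle, numeric(1), y = y)
  ord <- order(-su, seq_along(su))
  ord <- ord[su[ord] > delta]
  kept <- integer()
  for (j in ord) {
    dominated <- any(vapply(kept, function(i) {
      su_oracle(tab[[i]], tab[[j]]) >= su[j]
    }, logical(1)))
    if (!dominated) kept <- c(kept, j)
  }
  names(tab)[kept]
}

# Mann-Whitney AUC by direct pairwise comparison (ties count 1/2).
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# ICC(A,1) via R's linear-model ANOVA on the long two-way layout.
icc_anova_oracle <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- anova(lm(y ~ subj + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}
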