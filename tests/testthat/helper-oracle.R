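# Independent brute-force oracles, written against the rules from first
# principles (explicit loops, no reuse of package internals).

# recount an entire study and decide both phases from scratch
oracle_verdict <- function(dataset, variable, session, bands) {
  r <- dataset$readings
  r <- r[r$variable == variable & r$session == session, , drop = FALSE]
  ids <- sort(unique(r$participant_id))
  sel_all <- c()
  per_subject_b1 <- integer(0)
  for (id in ids) {
    v <- numeric(7)
    for (p in 1:7) {
      v[p] <- r$value[r$participant_id == id & r$position == p]
    }
    # the six successive-pair absolute differences, then keep the
    # smaller of the two around each test reading
    sel <- c(min(abs(v[2] - v[1]), abs(v[2] - v[3])),
             min(abs(v[4] - v[3]), abs(v[4] - v[5])),
             min(abs(v[6] - v[5]), abs(v[6] - v[7])))
    sel_all <- c(sel_all, sel)
    per_subject_b1 <- c(per_subject_b1, sum(sel <= bands[1]))
  }
  n <- length(ids)
  k <- round(n / 33)
  counts <- c(sum(sel_all <= bands[1]), sum(sel_all <= bands[2]),
              sum(sel_all <= bands[3]))
  two_of <- k * c(73, 87, 96)
  all_of <- k * c(65, 81, 93)
  p1 <- (sum(counts >= two_of) >= 2) && all(counts >= all_of)
  good <- sum(per_subject_b1 >= 2)
  bad <- sum(per_subject_b1 == 0)
  p2 <- (good >= k * 24) && (bad <= k * 3)
  list(phase1 = p1, phase2 = p2, counts = counts,
       good = good, bad = bad)
}

# two-way ANOVA ICC by explicit sums of squares over every cell
oracle_icc <- function(m, absolute = TRUE) {
  n <- nrow(m); k <- ncol(m)
  gm <- sum(m) / (n * k)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - gm)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - gm)^2
  sst <- 0
  for (i in 1:n) for (j in 1:k) sst <- sst + (m[i, j] - gm)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  if (absolute) {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# Pearson r by the explicit summation formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
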