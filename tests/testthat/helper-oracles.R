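# Independent, deliberately naive reference implementations of every
# registered index. Loop-based and written without reference to the package
# internals; used to verify oracle equivalence.

naive_embed <- function(x, m, tau = 1) {
  n <- length(x) - (m - 1) * tau
  E <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      E[i, j] <- x[i + (j - 1) * tau]
  E
}

# rank pattern with earlier-position-wins tie break, as a string
naive_pattern <- function(v) {
  r <- numeric(length(v))
  for (j in seq_along(v)) {
    r[j] <- 1
    for (k in seq_along(v)) {
      if (k == j) next
      if (v[k] < v[j] || (v[k] == v[j] && k < j)) r[j] <- r[j] + 1
    }
  }
  paste(r, collapse = "-")
}

naive_shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

naive_pen <- function(x, m = 3, tau = 1, normalize = TRUE) {
  E <- naive_embed(x, m, tau)
  pats <- apply(E, 1, naive_pattern)
  h <- naive_shannon(table(pats) / length(pats))
  if (normalize) h / log(factorial(m)) else h
}

naive_wpen <- function(x, m = 3, tau = 1, normalize = TRUE) {
  E <- naive_embed(x, m, tau)
  pats <- apply(E, 1, naive_pattern)
  w <- apply(E, 1, function(v) mean((v - mean(v))^2))
  pw <- tapply(w, pats, sum) / sum(w)
  h <- naive_shannon(pw)
  if (normalize) h / log(factorial(m)) else h
}

naive_cwpen <- function(x, m = 3, tau = 1) {
  naive_wpen(x, m + 1, tau, normalize = FALSE) -
    naive_wpen(x, m, tau, normalize = FALSE)
}

naive_swaps <- function(v) {
  # literal bubble sort
  cnt <- 0
  repeat {
    swapped <- FALSE
    for (i in seq_len(length(v) - 1)) {
      if (v[i] > v[i + 1]) {
        tmp <- v[i]; v[i] <- v[i + 1]; v[i + 1] <- tmp
        cnt <- cnt + 1
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  cnt
}

naive_bubben <- function(x, m = 3, tau = 1) {
  h2 <- function(mm) {
    s <- apply(naive_embed(x, mm, tau), 1, naive_swaps)
    p <- table(s) / length(s)
    -log(sum(p^2))
  }
  (h2(m + 1) - h2(m)) / log((m + 1) / (m - 1))
}

naive_coarse <- function(x, s) {
  k <- length(x) %/% s
  out <- numeric(k)
  for (i in seq_len(k)) out[i] <- mean(x[((i - 1) * s + 1):(i * s)])
  out
}

naive_mswpen <- function(x, m = 3, tau = 1) {
  scales <- 1:max(1, min(20, length(x) %/% 100))
  vals <- c()
  for (s in scales) {
    xs <- naive_coarse(x, s)
    if (length(xs) > (m - 1) * tau + 1)
      vals <- c(vals, naive_wpen(xs, m, tau, normalize = TRUE))
  }
  mean(vals)
}

naive_svden <- function(x, m = 3, tau = 1) {
  d <- svd(naive_embed(x, m, tau))$d
  p <- d / sum(d)
  naive_shannon(p)
}

naive_ll <- function(x) {
  s <- 0
  for (i in 1:(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s / (length(x) - 1)
}

naive_hjorth_mobility <- function(x) sqrt(var(diff(x)) / var(x))
naive_hjorth <- function(x)
  naive_hjorth_mobility(diff(x)) / naive_hjorth_mobility(x)

naive_atten <- function(x) {
  maxima <- minima <- integer(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima <- c(maxima, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) minima <- c(minima, i)
  }
  next_after <- function(from, to) {
    out <- c()
    for (f in from) {
      nx <- to[to > f]
      if (length(nx) > 0) out <- c(out, min(nx) - f)
    }
    out
  }
  sets <- list(diff(maxima), diff(minima),
               next_after(maxima, minima), next_after(minima, maxima))
  hs <- c()
  for (s in sets)
    if (length(s) > 0) hs <- c(hs, naive_shannon(table(s) / length(s)))
  mean(hs)
}

naive_apen <- function(x, m = 2, r = 0.2 * sd(x)) {
  phi <- function(mm) {
    E <- naive_embed(x, mm, 1)
    n <- nrow(E)
    cnt <- numeric(n)
    for (i in seq_len(n))
      cnt[i] <- sum(apply(abs(sweep(E, 2, E[i, ])), 1, max) <= r)
    mean(log(cnt / n))
  }
  phi(m) - phi(m + 1)
}

naive_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n_t <- length(x) - m
  count_pairs <- function(mm) {
    E <- naive_embed(x, mm, 1)[1:n_t, , drop = FALSE]
    tot <- 0
    for (i in seq_len(n_t))
      tot <- tot + sum(apply(abs(sweep(E, 2, E[i, ])), 1, max) <= r) - 1
    tot
  }
  -log(count_pairs(m + 1) / count_pairs(m))
}

naive_dispen <- function(x, m = 3, tau = 1, cl = 6) {
  y <- pnorm(x, mean(x), sd(x))
  z <- pmin(pmax(ceiling(y * cl), 1), cl)
  E <- naive_embed(z, m, tau)
  pats <- apply(E, 1, paste, collapse = "-")
  naive_shannon(table(pats) / length(pats)) / log(cl^m)
}

naive_shanen <- function(x, bins = 10) {
  br <- seq(min(x), max(x), length.out = bins + 1)
  cl <- numeric(length(x))
  for (i in seq_along(x))
    cl[i] <- max(1, min(bins, sum(x[i] >= br[-length(br)])))
  naive_shannon(table(cl) / length(x))
}

naive_higuchi <- function(x, kmax = 10) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in 1:kmax) {
    lm_vals <- c()
    for (m0 in 1:k) {
      idx <- seq(m0, n, by = k)
      if (length(idx) < 2) next
      L <- sum(abs(diff(x[idx]))) * (n - 1) / (k * (length(idx) - 1) * k)
      lm_vals <- c(lm_vals, L)
    }
    lk[k] <- mean(lm_vals)
  }
  -coef(lm(log(lk) ~ log(1:kmax)))[[2]]
}

naive_katz <- function(x) {
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  n <- length(x) - 1
  log10(n) / (log10(d / L) + log10(n))
}

naive_petrosian <- function(x) {
  d <- diff(x)
  nd <- 0
  for (i in 1:(length(d) - 1)) if (sign(d[i]) != sign(d[i + 1])) nd <- nd + 1
  n <- length(x)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

naive_enofen <- function(x, w = 10, s = 10) {
  k <- length(x) %/% w
  br <- seq(min(x), max(x), length.out = s + 1)
  bin_of <- function(v, b) max(1, min(length(b) - 1, findInterval(v, b, rightmost.closed = TRUE)))
  hs <- numeric(k)
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * w + 1):(i * w)]
    cls <- sapply(seg, bin_of, b = br)
    hs[i] <- naive_shannon(table(cls) / w)
  }
  if (diff(range(hs)) == 0) return(0)
  hbr <- seq(min(hs), max(hs), length.out = s + 1)
  cls <- sapply(hs, bin_of, b = hbr)
  naive_shannon(table(cls) / k)
}

# plain-loop MFDFA with per-segment lm() detrending
naive_mfdfa <- function(x, q = c(-5:-1, 1:5)) {
  n <- length(x)
  prof <- cumsum(x - mean(x))
  ws <- unique(round(exp(seq(log(10), log(max(12, n %/% 4)), length.out = 10))))
  ws <- ws[ws >= 10]
  log_fq <- matrix(NA, length(ws), length(q))
  for (wi in seq_along(ws)) {
    s <- ws[wi]
    k <- n %/% s
    f2 <- c()
    for (v in seq_len(k)) {
      seg <- prof[((v - 1) * s + 1):(v * s)]
      f2 <- c(f2, mean(resid(lm(seg ~ seq_len(s)))^2))
    }
    for (v in seq_len(k)) {
      seg <- prof[(n - v * s + 1):(n - (v - 1) * s)]
      f2 <- c(f2, mean(resid(lm(seg ~ seq_len(s)))^2))
    }
    f2 <- pmax(f2, .Machine$double.xmin)
    for (qi in seq_along(q))
      log_fq[wi, qi] <- log(mean(f2^(q[qi] / 2))) / q[qi]
  }
  h <- apply(log_fq, 2, function(y) coef(lm(y ~ log(ws)))[[2]])
  tau <- q * h - 1
  nq <- length(q)
  alpha <- rep(NA_real_, nq)
  f <- rep(NA_real_, nq)
  if (nq >= 3) {
    alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
    alpha[nq] <- (tau[nq] - tau[nq - 1]) / (q[nq] - q[nq - 1])
    for (i in 2:(nq - 1))
      alpha[i] <- (tau[i + 1] - tau[i - 1]) / (q[i + 1] - q[i - 1])
    f <- q * alpha - tau
  }
  list(q = q, h = h, alpha = alpha, f = f)
}

naive_mfdfa_features <- function(x) {
  sp <- naive_mfdfa(x)
  c(MFDFA_Max = sp$f[which.max(sp$alpha)],
    MFDFA_Width = max(sp$alpha) - min(sp$alpha),
    MFDFA_Mean = (max(sp$alpha) + min(sp$alpha)) / 2,
    MFDFA_Peak = sp$alpha[which.max(sp$f)],
    MFDFA_Increment = sum(diff(sp$h)^2))
}

naive_dfa <- function(x) {
  sp <- naive_mfdfa(x, q = 2)
  sp$h[1]
}

# full battery via the naive references, names matching the registry
naive_battery <- function(x) {
  c(CWPEn = naive_cwpen(x),
    LL = naive_ll(x),
    BubbEn = naive_bubben(x),
    MSWPEn = naive_mswpen(x),
    naive_mfdfa_features(x),
    Hjorth = naive_hjorth(x),
    SVDEn = naive_svden(x),
    AttEn = naive_atten(x),
    ApEn = naive_apen(x),
    SampEn = naive_sampen(x),
    PEn = naive_pen(x),
    WPEn = naive_wpen(x),
    DispEn = naive_dispen(x),
    ShanEn = naive_shanen(x),
    DFA = naive_dfa(x),
    HiguchiFD = naive_higuchi(x),
    KatzFD = naive_katz(x),
    PetrosianFD = naive_petrosian(x),
    HjorthMobility = naive_hjorth_mobility(x),
    EnofEn = naive_enofen(x))
}
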