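# Independent oracles. Each reimplements, from the definition, a quantity
# the package computes by another route. Keep these free of package
# internals beyond public constructors.

# --- global alignment identity: pure-R Gotoh DP ----------------------------
# Same conventions as the package route (gap of length L costs
# open + L * extend; tie preferences M > X > Y, open >= extend), but a
# fully separate implementation in R.
nw_oracle <- function(a, b, match = 1, mismatch = -1,
                      gap_open = -5, gap_extend = -1) {
  # canonical order, mirroring the package's symmetry rule
  if (nchar(a) < nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -Inf
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(NA_integer_, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- gap_open + gap_extend * (i - 1)
    tX[i, 1] <- if (i == 2) 0L else 1L
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- gap_open + gap_extend * (j - 1)
    tY[1, j] <- if (j == 2) 0L else 2L
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      if (cand[k] > NEG) { M[i, j] <- cand[k] + s; tM[i, j] <- k - 1L }
      xo <- max(M[i - 1, j], Y[i - 1, j]) + gap_open + gap_extend
      xe <- X[i - 1, j] + gap_extend
      if (xo >= xe) {
        X[i, j] <- xo
        tX[i, j] <- if (M[i - 1, j] >= Y[i - 1, j]) 0L else 2L
      } else { X[i, j] <- xe; tX[i, j] <- 1L }
      yo <- max(M[i, j - 1], X[i, j - 1]) + gap_open + gap_extend
      ye <- Y[i, j - 1] + gap_extend
      if (yo >= ye) {
        Y[i, j] <- yo
        tY[i, j] <- if (M[i, j - 1] >= X[i, j - 1]) 0L else 1L
      } else { Y[i, j] <- ye; tY[i, j] <- 2L }
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin) - 1L
  score <- fin[state + 1L]
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (state == 0L) {
      if (A[i] == B[j]) matches <- matches + 1L
      state <- tM[i + 1, j + 1]; i <- i - 1L; j <- j - 1L
    } else if (state == 1L) {
      state <- tX[i + 1, j + 1]; i <- i - 1L
    } else {
      state <- tY[i + 1, j + 1]; j <- j - 1L
    }
  }
  list(score = score, matches = matches, align_length = cols,
       identity = matches / cols)
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# --- Mann-Whitney exact p by full enumeration ------------------------------
mw_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(xi) {
    r <- rank(pooled)
    sum(r[xi]) - nx * (nx + 1) / 2
  }
  obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(xi)
    sum(rank(pooled)[xi]) - nx * (nx + 1) / 2)
  lo <- mean(us <= obs)
  hi <- mean(us >= obs)
  min(1, 2 * min(lo, hi))
}

# --- Kruskal-Wallis H from the textbook rank formula -----------------------
kw_oracle_h <- function(groups) {
  vals <- unlist(groups)
  n <- length(vals)
  r <- rank(vals)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), numeric(1))) -
    3 * (n + 1)
  ties <- table(vals)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# --- active-site concentration by brute-force grid search ------------------
# Same iterative beyond-intercept exclusion as the analytic route, but the
# line fit is a grid-search least-squares minimizer instead of OLS.
grid_site_oracle <- function(cabp, flux) {
  fit_grid <- function(c0, v) {
    a_grid <- seq(0, 2 * max(v), length.out = 4001)
    b_hi <- -1e-6
    b_lo <- -2 * max(v) / max(max(c0), 1)
    b_grid <- seq(b_lo, b_hi, length.out = 4001)
    # SSE(a, b) = sum(v^2) - 2a*Sv - 2b*Svc + n a^2 + 2ab*Sc + b^2*Scc
    n <- length(v)
    Sv <- sum(v); Svc <- sum(v * c0); Sc <- sum(c0); Scc <- sum(c0^2)
    sse <- outer(a_grid, b_grid, function(a, b)
      -2 * a * Sv - 2 * b * Svc + n * a^2 + 2 * a * b * Sc + b^2 * Scc)
    k <- arrayInd(which.min(sse), dim(sse))
    list(a = a_grid[k[1]], b = b_grid[k[2]])
  }
  use <- seq_along(cabp)
  repeat {
    f <- fit_grid(cabp[use], flux[use])
    im <- use[which.max(cabp[use])]
    if (f$a + f$b * cabp[im] <= 0 && length(use) > 3L) {
      use <- setdiff(use, im)
    } else break
  }
  -f$a / f$b
}

# --- exhaustive best split for a regression stump --------------------------
split_oracle <- function(X, y) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    for (cut in unique(X[, j])) {
      l <- y[X[, j] <= cut]; r <- y[X[, j] > cut]
      if (!length(l) || !length(r)) next
      sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
      if (is.null(best) || sse < best$sse - 1e-12)
        best <- list(feature = j, sse = sse)
    }
  }
  best
}

# --- tiny shared fixtures --------------------------------------------------
worked_points <- function() {
  data.frame(cabp_nM = c(0, 0, 10, 20, 30, 90),
             flux_nM_s = c(10, 10, 8, 6, 4, 0))
}
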