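# Independent brute-force reference implementations used to verify the
# fast paths. Deliberately naive: plain loops, no shared code with R/.

reflect_idx <- function(i, n) {
  while (any(bad <- i < 1 | i > n)) {
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
  }
  i
}

# per-pixel neighborhood median with reflected borders
oracle_median <- function(x, k) {
  h <- k %/% 2
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- reflect_idx(r + (-h:h), nr)
    cc <- reflect_idx(c + (-h:h), nc)
    out[r, c] <- median(x[rr, cc])
  }
  out
}

# exhaustive Otsu: the split (0-based, after bin t+1) minimizing total
# within-class variance of bin indices weighted by counts; first minimum
oracle_otsu_bin <- function(counts) {
  k <- length(counts)
  v <- seq_len(k)
  best <- Inf; best_t <- NA_integer_
  for (t in 0:(k - 2)) {
    i0 <- seq_len(t + 1); i1 <- (t + 2):k
    n0 <- sum(counts[i0]); n1 <- sum(counts[i1])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[i0] * v[i0]) / n0
    m1 <- sum(counts[i1] * v[i1]) / n1
    w <- sum(counts[i0] * (v[i0] - m0)^2) + sum(counts[i1] * (v[i1] - m1)^2)
    if (w < best - 1e-12) { best <- w; best_t <- t }
  }
  best_t
}

# flood-fill component labeling + small-object removal
oracle_clean <- function(binary, cornea_mask, min_px, connectivity) {
  m <- binary & cornea_mask
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!m[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack_r <- r0; stack_c <- c0
    lab[r0, c0] <- nxt
    while (length(stack_r)) {
      pr <- stack_r[length(stack_r)]; pc <- stack_c[length(stack_c)]
      stack_r <- stack_r[-length(stack_r)]
      stack_c <- stack_c[-length(stack_c)]
      for (o in offs) {
        r <- pr + o[1]; c <- pc + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack_r <- c(stack_r, r); stack_c <- c(stack_c, c)
        }
      }
    }
  }
  if (nxt == 0L) return(m)
  sizes <- tabulate(lab[lab > 0L], nxt)
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nr, nc)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y); n <- length(pooled)
  idx <- utils::combn(n, n1)
  u_of <- function(sel) sum(rank(pooled)[sel]) - n1 * (n1 + 1) / 2
  us <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# log-rank observed/expected per group by explicit risk-set enumeration
oracle_logrank_oe <- function(times, events, groups) {
  g <- as.factor(groups)
  lev <- levels(g)
  obs <- setNames(numeric(length(lev)), lev)
  exp_ <- setNames(numeric(length(lev)), lev)
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    d <- events == 1 & times == t
    n_t <- sum(at_risk); d_t <- sum(d)
    for (l in lev) {
      obs[l] <- obs[l] + sum(d & g == l)
      exp_[l] <- exp_[l] + d_t * sum(at_risk & g == l) / n_t
    }
  }
  list(observed = obs, expected = exp_)
}

# a small ragged test polygon (simple, non-convex)
ragged_polygon <- function(seed = 1, n = 9, r_base = 20, cx = 32, cy = 32) {
  set.seed(seed)
  ang <- sort(runif(n, 0, 2 * pi))
  r <- r_base * runif(n, 0.5, 1)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}
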