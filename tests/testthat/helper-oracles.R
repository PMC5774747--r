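# Independent brute-force oracles, deliberately written as plain scalar
# loops so they share no code path with the implementation.

# distance from every voxel centre to the nearest target-surface voxel
# centre, by explicit double loop
bf_surface_distance <- function(structures) {
  grid <- structures$grid
  P <- voxel_centers(grid)
  tg <- target_union(structures)
  s <- grid$shape
  # 6-neighbourhood restricted to non-degenerate axes (a length-1 axis
  # has no neighbours), out-of-grid counts as non-target
  deltas <- list()
  for (ax in 1:3) {
    if (s[ax] > 1) {
      for (sgn in c(1L, -1L)) {
        d <- c(0L, 0L, 0L); d[ax] <- sgn
        deltas[[length(deltas) + 1]] <- d
      }
    }
  }
  surf <- logical(length(tg))
  for (k in which(tg)) {
    i <- (k - 1) %% s[1]
    j <- ((k - 1) %/% s[1]) %% s[2]
    l <- (k - 1) %/% (s[1] * s[2])
    nb_out <- FALSE
    for (d in deltas) {
      ii <- i + d[1]; jj <- j + d[2]; ll <- l + d[3]
      if (ii < 0 || ii >= s[1] || jj < 0 || jj >= s[2] ||
          ll < 0 || ll >= s[3]) {
        nb_out <- TRUE
      } else if (!tg[ii + s[1] * (jj + s[2] * ll) + 1]) {
        nb_out <- TRUE
      }
    }
    surf[k] <- nb_out
  }
  S <- which(surf)
  out <- numeric(nrow(P))
  for (k in seq_len(nrow(P))) {
    best <- Inf
    for (m in S) {
      d2 <- sum((P[k, ] - P[m, ])^2)
      if (d2 < best) best <- d2
    }
    out[k] <- sqrt(best)
  }
  out
}

# cumulative DVH by direct counting at each bin edge
bf_dvh_volume <- function(doses, edges) {
  vapply(edges, function(e) 100 * sum(doses >= e) / length(doses),
         numeric(1))
}

# dose to the hottest v% by sorting and linear rank interpolation
bf_dose_at_volume <- function(doses, v) {
  ds <- sort(doses, decreasing = TRUE)
  n <- length(ds)
  h <- v / 100 * n
  if (h <= 1) return(ds[1])
  i <- floor(h)
  if (i >= n) return(ds[n])
  ds[i] * (1 - (h - i)) + ds[i + 1] * (h - i)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences (no ties, no zeros)
bf_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[1:n]
    vs[code + 1] <- sum(r[bits == 1L])
  }
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  list(statistic = v_obs, p.value = min(1, 2 * min(p_le, p_ge)))
}

# naive two-pass population standard deviation
bf_pop_sd <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / length(x))
}
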