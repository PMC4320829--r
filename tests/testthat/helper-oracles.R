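# Independent reference implementations used to cross-check the package.
# These are deliberately written as literal, slow simulations of the
# definitions and share no code with the implementations under test.

# --- max-interval burst detection: direct sequential phase simulation ----
oracle_bursts <- function(times, p) {
  n <- length(times)
  cand <- list()
  i <- 1
  # Phase 1: scan; a burst opens at an ISI < max_begin_isi and runs while
  # ISIs < max_end_isi
  while (i < n) {
    if (times[i + 1] - times[i] < p$max_begin_isi) {
      j <- i + 1
      while (j < n && times[j + 1] - times[j] < p$max_end_isi) j <- j + 1
      cand[[length(cand) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  # Phase 2: merge candidates with gap < min_ibi
  merged <- list()
  for (b in cand) {
    if (length(merged)) {
      prev <- merged[[length(merged)]]
      if (times[b[1]] - times[prev[2]] < p$min_ibi) {
        merged[[length(merged)]] <- c(prev[1], b[2])
        next
      }
    }
    merged[[length(merged) + 1]] <- b
  }
  # Phase 3: duration / spike-count filter
  keep <- Filter(function(b) {
    (b[2] - b[1] + 1) >= p$min_spikes &&
      (times[b[2]] - times[b[1]]) >= p$min_duration
  }, merged)
  if (!length(keep))
    return(data.frame(start_index = integer(), end_index = integer()))
  data.frame(start_index = as.integer(vapply(keep, `[`, numeric(1), 1)),
             end_index = as.integer(vapply(keep, `[`, numeric(1), 2)))
}

# --- STTC: O(n*m) oracle ------------------------------------------------
# P by pairwise comparison; T by explicit interval-union sweep.
oracle_sttc <- function(a, b, dt) {
  if (!length(a$times) || !length(b$times)) return(NA_real_)
  prop <- function(x, ref) {
    hit <- vapply(x, function(t) any(abs(t - ref) <= dt), logical(1))
    mean(hit)
  }
  cover <- function(x, t0, t1) {
    iv <- cbind(pmax(x - dt, t0), pmin(x + dt, t1))
    tot <- 0
    cur <- iv[1, ]
    if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
      if (iv[k, 1] <= cur[2]) cur[2] <- max(cur[2], iv[k, 2])
      else { tot <- tot + cur[2] - cur[1]; cur <- iv[k, ] }
    }
    (tot + cur[2] - cur[1]) / (t1 - t0)
  }
  TA <- cover(a$times, a$t_start, a$t_stop)
  TB <- cover(b$times, b$t_start, b$t_stop)
  PA <- prop(a$times, b$times)
  PB <- prop(b$times, a$times)
  term <- function(P, T) if (1 - P * T == 0) 0 else (P - T) / (1 - P * T)
  0.5 * (term(PA, TB) + term(PB, TA))
}

# --- Mann-Whitney: full enumeration of group assignments ----------------
# Two-sided p = probability, under random assignment, of a U at least as
# extreme (in either tail) as observed.
oracle_mw_p <- function(a, b) {
  m <- length(a); n <- length(b)
  v <- c(a, b)
  u_of <- function(idx) {
    aa <- v[idx]; bb <- v[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  obs <- u_of(seq_len(m))
  us <- apply(utils::combn(m + n, m), 2, u_of)
  dev <- abs(us - m * n / 2)
  mean(dev >= abs(obs - m * n / 2) - 1e-12)
}

# --- random spike trains -------------------------------------------------
random_train <- function(n_max = 200, t_stop = 60, bursty = TRUE) {
  n <- sample.int(n_max, 1)
  t <- if (bursty) {
    centers <- runif(max(1, rpois(1, 5)), 0, t_stop)
    sort(abs(rnorm(n, sample(centers, n, replace = TRUE), 0.3))) %% t_stop
  } else {
    runif(n, 0, t_stop)
  }
  t <- sort(unique(round(t, 6)))
  spike_train(t, t_start = 0, t_stop = t_stop)
}
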