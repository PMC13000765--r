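# Brute-force reference implementations of the coincidence acceptance
# rules, written as literal loops over all pairs/subsets so they stay
# independent of the vectorized single-pass code they check.

oracle_doubles <- function(t, tau, scheme) {
  n <- length(t)
  out <- NULL
  tp <- function(i) if (i >= 1 && i <= n) t[i] else if (i < 1) -Inf else Inf
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dt <- t[j] - t[i]
      if (!(dt > 0 && dt <= tau)) next
      ok <- switch(scheme,
        vno = TRUE,
        vbetween = j == i + 1,
        vinner = j == i + 1 && tp(i + 2) - t[i] > tau && t[j] - tp(i - 1) > tau,
        vouter = j == i + 1 && t[i] - tp(i - 1) > tau && tp(i + 2) - t[j] > tau)
      if (ok) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

oracle_multiples <- function(t, tau, m, scheme) {
  n <- length(t)
  tp <- function(i) if (i >= 1 && i <= n) t[i] else if (i < 1) -Inf else Inf
  out <- NULL
  if (scheme == "vno") {
    if (n >= m) {
      for (rows in utils::combn(n, m, simplify = FALSE)) {
        span <- t[rows[m]] - t[rows[1]]
        if (span > 0 && span <= tau) out <- rbind(out, rows)
      }
    }
  } else {
    for (i in seq_len(max(0, n - m + 1))) {
      last <- i + m - 1
      span <- t[last] - t[i]
      if (!(span > 0 && span <= tau)) next
      ok <- switch(scheme,
        vbetween = TRUE,
        vinner = tp(i + m) - t[i] > tau && t[last] - tp(i - 1) > tau,
        vouter = t[i] - tp(i - 1) > tau && tp(i + m) - t[last] > tau)
      if (ok) out <- rbind(out, i:last)
    }
  }
  if (is.null(out)) matrix(integer(), 0, m) else unname(out)
}

# literal random-coincidence counter from decay labels
oracle_ground_truth <- function(stream, tau, scheme, target) {
  t <- stream$events$time_ps
  id <- stream$events$decay_id
  if (target == "doubles") {
    mm <- oracle_doubles(t, tau, scheme)
    if (!nrow(mm)) return(0L)
    sum(id[mm[, 1]] != id[mm[, 2]])
  } else {
    mm <- oracle_multiples(t, tau, 3L, scheme)
    if (!nrow(mm)) return(0L)
    ndec <- apply(mm, 1, function(r) length(unique(id[r])))
    sum(ndec == if (target == "triples_2decay") 2L else 3L)
  }
}
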