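# Independent brute-force reference for the acACS encoder: explicit
# per-position table scans and a literal double loop over the lagged
# squared differences. Shares no code path with the package encoder.

oracle_series <- function(sequence, ss, table, atom) {
  res <- strsplit(sequence, "")[[1]]
  kst <- strsplit(ss, "")[[1]]
  vapply(seq_along(res), function(l) {
    row <- table[table$atom == atom & table$residue == res[l] &
                   table$ss == kst[l], ]
    stopifnot(nrow(row) == 1L)
    row$mean_ppm
  }, numeric(1))
}

oracle_theta <- function(series, lam) {
  L <- length(series)
  acc <- 0
  for (l in seq_len(L - lam)) {
    acc <- acc + (series[l] - series[l + lam])^2
  }
  acc / (L - lam)
}

oracle_acacs <- function(sequence, ss, table, atoms, lambda) {
  out <- numeric(0)
  for (atom in atoms) {
    s <- oracle_series(sequence, ss, table, atom)
    block <- sum(s) / length(s)
    for (lam in seq_len(lambda)) {
      block <- c(block, oracle_theta(s, lam))
    }
    out <- c(out, block)
  }
  out
}

# greedy longest-first redundancy filter recomputed from a brute-force
# all-pairs identity matrix
oracle_identity_filter <- function(samples, max_identity, pid_fun) {
  n <- nrow(samples)
  idm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) idm[i, j] <- pid_fun(samples$sequence[i],
                                       samples$sequence[j])
    }
  }
  ord <- order(-nchar(samples$sequence), seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    if (all(idm[i, kept] <= max_identity)) kept <- c(kept, i)
  }
  sort(kept)
}
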