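# Independent straight-line oracle for the contrast scorer.
#
# Re-derives every stage (normalization, fold change, rank-window sd, z,
# gene aggregation, re-standardization, one-tailed p, BH) with explicit
# loops and textbook formulas, sharing no code with the package
# implementation. Single control/treated pair only.

oracle_bh <- function(p) {
  # Benjamini-Hochberg step-up by direct enumeration
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(q[i:n], 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

oracle_run_contrast <- function(table, control, treated,
                                pseudocount = 5, scale = 1e7,
                                window, min_std = 1e-6) {
  cc <- table[[control]]
  tt <- table[[treated]]
  nc <- numeric(length(cc))
  nt <- numeric(length(tt))
  for (i in seq_along(cc)) nc[i] <- pseudocount + cc[i] * scale / sum(cc)
  for (i in seq_along(tt)) nt[i] <- pseudocount + tt[i] * scale / sum(tt)
  fc <- log2(nt / nc)

  N <- nrow(table)
  ord <- order(-nc, table$guide_id, method = "radix")
  std <- numeric(N)
  for (r in seq_len(N)) {
    win <- ord[max(1, r - window):min(N, r + window)]
    std[ord[r]] <- max(stats::sd(fc[win]), min_std)
  }
  z <- fc / std

  units <- sort(unique(table$gene))
  sumZ <- numeric(length(units))
  numObs <- integer(length(units))
  for (j in seq_along(units)) {
    sel <- table$gene == units[j]
    sumZ[j] <- sum(z[sel])
    numObs[j] <- sum(sel)
  }
  raw <- sumZ / sqrt(numObs)
  normZ <- (raw - mean(raw)) / stats::sd(raw)
  p_left <- stats::pnorm(normZ)
  p_right <- 1 - p_left
  df <- data.frame(unit = units, numObs = numObs, sumZ = sumZ, normZ = normZ,
                   p_left = p_left, p_right = p_right,
                   fdr_left = oracle_bh(p_left), fdr_right = oracle_bh(p_right),
                   stringsAsFactors = FALSE)
  df[order(df$normZ, df$unit, method = "radix"), ]
}
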