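# Independent oracles used across test files. These deliberately re-derive
# quantities from first principles (double loops, explicit resampling) so the
# optimized implementations are checked against something they do not share
# code with.

# Brute-force nucleotide diversity: ordered double loop over all sequence
# pairs on the raw character matrix (after the same complete-deletion rule,
# applied longhand).
oracle_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  drop <- apply(m, 2, function(col) any(col %in% c("-", "N")))
  m <- m[, !drop, drop = FALSE]
  n <- nrow(m)
  L <- ncol(m)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) tot <- tot + sum(m[i, ] != m[j, ]) / L
    }
  }
  # each unordered pair counted twice; x_i = 1/n per sequence
  n / (n - 1) * tot / n^2
}

# Explicit percentile-bootstrap of the median with the same seed stream the
# package documents (B draws of size n with replacement, type-7 quantiles).
oracle_boot <- function(values, B, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  meds <- numeric(B)
  for (b in seq_len(B)) {
    meds[b] <- median(sample(values, length(values), replace = TRUE))
  }
  unname(quantile(meds, c(0.5, 0.025, 0.975), type = 7))
}

# Hand-iterated Schaefer recurrence.
oracle_schaefer <- function(r, k, catches, B0) {
  B <- B0
  out <- B0
  for (C in catches) {
    B <- B + r * B * (1 - B / k) - C
    out <- c(out, B)
  }
  out
}

# Temporary FASTA writer for read_alignment tests.
write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta"),
                        width = 0) {
  lines <- character(0)
  for (i in seq_along(ids)) {
    s <- seqs[i]
    body <- if (width > 0) {
      starts <- seq(1, nchar(s), by = width)
      vapply(starts, function(st) substr(s, st, min(st + width - 1, nchar(s))),
             character(1))
    } else s
    lines <- c(lines, paste0(">", ids[i]), body)
  }
  writeLines(lines, path)
  path
}
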