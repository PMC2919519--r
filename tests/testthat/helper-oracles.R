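# Independent reference implementations used as oracles. They deliberately
# avoid the package's contingency-table shortcut: everything is recomputed
# from full-length vectors with stats::cor.

# relabel original bin labels onto the merged structure given the surviving
# upper bin indices
relabel_oracle <- function(labels, upper) {
  map <- rep(seq_along(upper), diff(c(0L, upper)))
  map[labels]
}

# naive greedy quantize-and-merge: every candidate correlation recomputed
# from scratch on n-length relabelled vectors
naive_greedy_qcc <- function(x, y, B0, eps = 1e-12) {
  lx <- quantize_equal_count(x, B0)
  ly <- quantize_equal_count(y, B0)
  upper <- seq_len(B0)
  cur <- stats::cor(relabel_oracle(lx, upper), relabel_oracle(ly, upper))
  trace_bin <- integer(0)
  trace_cor <- numeric(0)
  while (length(upper) > 2L) {
    B <- length(upper)
    cand <- vapply(seq_len(B - 1L), function(k) {
      up2 <- upper[-k]
      suppressWarnings(
        stats::cor(relabel_oracle(lx, up2), relabel_oracle(ly, up2)))
    }, numeric(1))
    ok <- which(!is.na(cand))
    if (!length(ok)) break
    mx <- max(cand[ok])
    if (mx <= cur + eps) break
    k <- min(ok[cand[ok] >= mx - eps])
    upper <- upper[-k]
    cur <- cand[k]
    trace_bin <- c(trace_bin, k)
    trace_cor <- c(trace_cor, cur)
  }
  list(qcc = cur, trace_bin = trace_bin, trace_cor = trace_cor,
       final_B = length(upper))
}

# O(n * B^2) nested-loop contingency counter
naive_contingency <- function(lx, ly, B) {
  out <- matrix(0L, B, B)
  for (a in seq_len(B)) for (b in seq_len(B)) {
    out[a, b] <- sum(lx == a & ly == b)
  }
  out
}

# expand a contingency table back into label vectors
expand_table <- function(tab) {
  B <- nrow(tab)
  xs <- integer(0); ys <- integer(0)
  for (a in seq_len(B)) for (b in seq_len(B)) {
    if (tab[a, b] > 0) {
      xs <- c(xs, rep.int(a, tab[a, b]))
      ys <- c(ys, rep.int(b, tab[a, b]))
    }
  }
  list(x = xs, y = ys)
}

# a random contingency table with positive marginals
random_table <- function(B, total) {
  repeat {
    tab <- matrix(stats::rmultinom(1, total, rep(1, B * B)), B, B)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

write_bedgraph_lines <- function(path, chrom, start, end, value) {
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start, end,
                     format(value, trim = TRUE)), path)
  path
}
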