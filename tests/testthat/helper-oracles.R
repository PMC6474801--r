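# Independent oracles used to cross-check the package implementation.
# These deliberately use naive algorithms (queue flood fill, exhaustive
# search, textbook formulas) and share no code with the package internals.

# Queue-based flood-fill connected-component labeling (8- or 4-connectivity).
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition iff the label pairs are in
# bijection.
same_partition <- function(a, b) {
  if (any((a > 0) != (b > 0))) return(FALSE)
  idx <- a > 0
  pairs <- unique(cbind(a[idx], b[idx]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# Exhaustive-search Renyi/Shannon entropy threshold: evaluates the class
# entropy sum at every cut directly from the definitions.
renyi_threshold_oracle <- function(p, alpha) {
  p <- p / sum(p)
  n <- length(p)
  best <- -Inf; best_t <- NA_integer_
  for (t in 1:(n - 1)) {
    P1 <- sum(p[1:t]); P2 <- 1 - P1
    if (P1 <= 0 || P2 <= 1e-15) next
    q1 <- p[1:t] / P1; q2 <- p[(t + 1):n] / P2
    H <- function(q) {
      q <- q[q > 0]
      if (abs(alpha - 1) < 1e-9) -sum(q * log(q))
      else log(sum(q^alpha)) / (1 - alpha)
    }
    val <- H(q1) + H(q2)
    if (val > best + 1e-12) { best <- val; best_t <- t }
  }
  if (is.na(best_t)) stop("oracle: degenerate histogram")
  best_t
}

# Textbook pooled-variance two-sample t statistic and p value.
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Small deterministic binary fixture with known 8-connected components.
rectangle_mask <- function(nr, nc, rects) {
  m <- matrix(FALSE, nr, nc)
  for (r in rects) m[r[1]:r[2], r[3]:r[4]] <- TRUE
  m
}
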