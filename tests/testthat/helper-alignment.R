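# Independent dynamic-programming alignment oracle used to cross-check the
# package's identity computations: unit scoring (match +1, mismatch -1,
# gap -1 per column), global or ends-free (overlap) mode. Deliberately
# written without Biostrings.

oracle_align <- function(a, b, mode = c("global", "overlap")) {
  mode <- match.arg(mode)
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A)
  m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 0 diag, 1 up (gap in b), 2 left (gap in a)
  if (mode == "global") {
    S[, 1] <- -(0:n)
    S[1, ] <- -(0:m)
    P[-1, 1] <- 1L
    P[1, -1] <- 2L
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + if (A[i] == B[j]) 1 else -1
      u <- S[i, j + 1] - 1
      l <- S[i + 1, j] - 1
      best <- max(d, u, l)
      S[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (best == d) 0L else if (best == u) 1L else 2L
    }
  }
  if (mode == "global") {
    ei <- n + 1L
    ej <- m + 1L
  } else {
    lastcol <- S[, m + 1]
    lastrow <- S[n + 1, ]
    if (max(lastcol) >= max(lastrow)) {
      ei <- which.max(lastcol)
      ej <- m + 1L
    } else {
      ei <- n + 1L
      ej <- which.max(lastrow)
    }
  }
  i <- ei
  j <- ej
  matches <- 0L
  cols <- 0L
  while (i > 1L || j > 1L) {
    if (mode == "overlap" && (i == 1L || j == 1L)) break
    p <- P[i, j]
    if (p == 0L) {
      matches <- matches + (A[i - 1L] == B[j - 1L])
      i <- i - 1L
      j <- j - 1L
    } else if (p == 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    cols <- cols + 1L
  }
  list(matches = matches, aln_len = cols,
       identity = if (cols > 0) matches / cols else 0,
       span_a = ei - i, span_b = ej - j)
}

oracle_global_identity <- function(a, b) oracle_align(a, b, "global")$identity

# random sequence utilities for fixtures
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, n_subs) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(b), n_subs)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}
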