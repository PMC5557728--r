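# Independent oracles used across the suite. These are deliberately naive
# implementations (quadratic DP, exhaustive enumeration, brute-force pair
# expansion) kept separate from the package's code paths.

# Affine-gap pairwise alignment score oracle (Gotoh), same scoring scheme the
# package documents: match +1, mismatch -1, gap open -2, gap extend -1 per
# gap base (a k-base gap costs 2 + k). N never matches.
oracle_score <- function(a, b, type = c("global", "local"),
                         match = 1, mismatch = -1, open = 2, ext = 1) {
  type <- match.arg(type)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  if (type == "local") { M[1, ] <- 0; M[, 1] <- 0 }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j] && A[i] %in% c("A", "C", "G", "T")) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      if (type == "local") M[i + 1, j + 1] <- max(0, M[i + 1, j + 1])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  if (type == "global") max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  else max(M)
}

# Brute-force nucleotide diversity: materialise each haplotype `count` times
# and average pairwise per-site differences over all C(n,2) pairs.
oracle_pi <- function(alignment, counts,
                      policy = c("gap_as_event", "complete_deletion")) {
  policy <- match.arg(policy)
  rows <- rep(alignment, counts)
  mat <- do.call(rbind, strsplit(rows, ""))
  if (policy == "complete_deletion") {
    mat <- mat[, colSums(mat == "-") == 0, drop = FALSE]
  }
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mat[i, ]; b <- mat[j, ]
      use <- a != "N" & b != "N"
      a <- a[use]; b <- b[use]
      ga <- a == "-"; gb <- b == "-"
      bases <- !ga & !gb
      d <- sum(a[bases] != b[bases])
      len <- sum(bases)
      if (policy == "gap_as_event") {
        r <- rle(ifelse(ga & !gb, "a", ifelse(gb & !ga, "b", ".")))
        d <- d + sum(r$values != ".")
        len <- len + sum(xor(ga, gb))
      }
      vals <- c(vals, if (len > 0) d / len else NA_real_)
    }
  }
  mean(vals, na.rm = TRUE)
}

# Exhaustive minimum spanning tree weight: enumerate all (n-1)-edge subsets
# of the complete graph and keep the lightest one that spans.
oracle_mst_weight <- function(dm) {
  n <- nrow(dm)
  if (n == 1) return(0)
  pairs <- t(utils::combn(n, 2))
  w <- dm[pairs]
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}

# Enumerate all candidate overlaps for a mate pair, mirroring the documented
# merge contract but written independently of the package code.
oracle_merge <- function(m1, m2, min_overlap, max_mm_frac) {
  rc <- satlib::revcomp(m2)
  s1 <- strsplit(m1, "")[[1]]; s2 <- strsplit(rc, "")[[1]]
  L1 <- length(s1); L2 <- length(s2)
  if (min_overlap > min(L1, L2)) return(NULL)
  cand <- do.call(rbind, lapply(seq(min_overlap, min(L1, L2)), function(o) {
    mm <- sum(s1[(L1 - o + 1):L1] != s2[1:o])
    c(o = o, mm = mm, f = mm / o)
  }))
  cand <- cand[cand[, "f"] == min(cand[, "f"]), , drop = FALSE]
  best <- cand[which.max(cand[, "o"]), ]
  if (best[["f"]] > max_mm_frac) return(NULL)
  list(o = best[["o"]], mm = best[["mm"]])
}

# Count mutational steps between two gapped rows: base mismatches plus gap
# runs present in exactly one row.
oracle_pair_steps <- function(x, y) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  ga <- a == "-"; gb <- b == "-"
  bases <- !ga & !gb
  r <- rle(ifelse(ga & !gb, "a", ifelse(gb & !ga, "b", ".")))
  sum(a[bases] != b[bases]) + sum(r$values != ".")
}

rotate <- function(x, k) {
  L <- nchar(x); k <- k %% L
  if (k == 0) return(x)
  paste0(substr(x, k + 1, L), substr(x, 1, k))
}
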