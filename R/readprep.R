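#' Randomly subsample read pairs
#'
#' Uniform sampling without replacement, keeping original order of the kept
#' pairs. If `n` is at least the number of pairs, all pairs are returned.
#'
#' @param pairs Read-pair tibble (see [read_fastq_pairs()]).
#' @param n Number of pairs to keep (>= 0).
#' @param seed Integer seed.
#' @return Subsampled read-pair tibble.
#' @export
subsample_pairs <- function(pairs, n, seed = 1L) {
  if (n < 0) stop_param("subsample size must be >= 0")
  if (n >= nrow(pairs)) return(pairs)
  keep <- withr::with_seed(seed, sort(sample.int(nrow(pairs), n)))
  pairs[keep, , drop = FALSE]
}

#' Merge one read pair by overlap
#'
#' Reverse-complements mate 2 and scans every candidate overlap length
#' `>= min_overlap` between the mate-1 suffix and the reverse-complemented
#' mate-2 prefix, choosing the overlap with the lowest mismatch fraction
#' (ties go to the longest overlap). Mismatched overlap bases are resolved to
#' the higher-quality base (quality ties to the mate-1 base); N always counts
#' as a mismatch. An irreconcilable pair yields a no-merge result, not an
#' error.
#'
#' @param mate1,mate2 DNA strings (mate 2 in raw sequencing orientation).
#' @param qual1,qual2 Phred+33 quality strings; default constant quality.
#' @param min_overlap Minimum overlap length (>= 1).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the
#'   overlap.
#' @return A list with elements `merged` (logical), `sequence`, `overlap`,
#'   `mismatches` (`NA` when unmerged).
#' @export
#' @examples
#' merge_pair("AAAACCCC", "CCCCGGGG", min_overlap = 4)
merge_pair <- function(mate1, mate2, qual1 = NULL, qual2 = NULL,
                       min_overlap = 20L, max_mismatch_frac = 0.10) {
  if (min_overlap < 1) stop_param("min_overlap must be >= 1")
  if (is.null(qual1)) qual1 <- strrep("F", nchar(mate1))
  if (is.null(qual2)) qual2 <- strrep("F", nchar(mate2))
  if (nchar(mate1) == 0L || nchar(mate2) == 0L) stop_param("mates must be non-empty")
  assert_dna(c(mate1, mate2), what = "mate")

  s1 <- strsplit(mate1, "", fixed = TRUE)[[1]]
  s2 <- strsplit(revcomp(mate2), "", fixed = TRUE)[[1]]
  q1 <- utf8ToInt(qual1)
  q2 <- rev(utf8ToInt(qual2))
  L1 <- length(s1); L2 <- length(s2)
  no_merge <- list(merged = FALSE, sequence = NA_character_,
                   overlap = NA_integer_, mismatches = NA_integer_)
  omax <- min(L1, L2)
  if (min_overlap > omax) return(no_merge)

  cand <- min_overlap:omax
  mm <- vapply(cand, function(o) {
    a <- s1[(L1 - o + 1L):L1]
    b <- s2[seq_len(o)]
    sum(a != b | a == "N" | b == "N")
  }, integer(1))
  frac <- mm / cand
  best <- which(frac == min(frac))
  best <- best[length(best)]  # ties -> longest overlap
  if (frac[best] > max_mismatch_frac) return(no_merge)

  o <- cand[best]
  ov1 <- (L1 - o + 1L):L1
  a <- s1[ov1]; b <- s2[seq_len(o)]
  diff <- which(a != b)
  if (length(diff)) {
    use2 <- q2[diff] > q1[ov1[diff]]
    a[diff[use2]] <- b[diff[use2]]
  }
  tail2 <- if (o < L2) s2[(o + 1L):L2] else character(0)
  merged <- paste(c(s1[seq_len(L1 - o)], a, tail2), collapse = "")
  list(merged = TRUE, sequence = merged, overlap = o,
       mismatches = as.integer(mm[best]))
}

#' Merge all read pairs in a table
#'
#' Applies [merge_pair()] row-wise.
#'
#' @param pairs Read-pair tibble.
#' @inheritParams merge_pair
#' @return Tibble with columns `id`, `merged`, `sequence`, `overlap`,
#'   `mismatches`; unmerged pairs keep `merged = FALSE` with `NA` fields.
#' @export
merge_pairs <- function(pairs, min_overlap = 20L, max_mismatch_frac = 0.10) {
  res <- purrr::pmap(
    list(pairs$mate1, pairs$mate2, pairs$qual1, pairs$qual2),
    function(m1, m2, q1, q2) {
      merge_pair(m1, m2, q1, q2, min_overlap = min_overlap,
                 max_mismatch_frac = max_mismatch_frac)
    }
  )
  tibble(
    id = pairs$id,
    merged = purrr::map_lgl(res, "merged"),
    sequence = purrr::map_chr(res, "sequence"),
    overlap = purrr::map_int(res, "overlap"),
    mismatches = purrr::map_int(res, "mismatches")
  )
}

#' Select reads homologous to a satellite consensus
#'
#' Aligns each query locally against the doubled consensus (tandem repeats
#' are circular: a read may straddle the arbitrary consensus start) on both
#' strands and calls a hit when the best alignment reaches `min_identity`
#' over at least `min_aligned` columns. Queries shorter than `min_aligned`
#' are skipped with a warning; queries with more than 10% N are dropped.
#'
#' @param queries Tibble with columns `id` and `sequence`, or a character
#'   vector of sequences.
#' @param consensus A `sat_consensus` (see [sat_consensus()]) or DNA string.
#' @param min_identity Minimum identity (matches / alignment columns, gaps
#'   counting as columns).
#' @param min_aligned Minimum number of alignment columns.
#' @return Tibble with columns `id`, `identity`, `aligned`, `strand`, `hit`.
#' @export
select_homologous <- function(queries, consensus, min_identity = 0.70,
                              min_aligned = 50L) {
  if (is.character(queries)) {
    queries <- tibble(id = sprintf("q%06d", seq_along(queries)),
                      sequence = queries)
  }
  cons <- consensus_sequence(consensus)
  if (nchar(cons) == 0L) stop_param("consensus must be non-empty")
  n <- nrow(queries)
  out <- tibble(id = queries$id, identity = NA_real_, aligned = NA_integer_,
                strand = NA_character_, hit = FALSE)
  if (n == 0L) return(out)

  n_frac <- stringr::str_count(queries$sequence, "N") / nchar(queries$sequence)
  short <- nchar(queries$sequence) < min_aligned
  if (any(short)) {
    warn(sprintf("%d quer%s shorter than min_aligned were skipped",
                 sum(short), if (sum(short) == 1) "y" else "ies"))
  }
  usable <- which(!short & n_frac <= 0.10)
  if (length(usable) == 0L) return(out)

  doubled <- strrep(cons, 2L)
  fwd <- align_many(queries$sequence[usable], doubled, type = "local")
  rev <- align_many(revcomp(queries$sequence[usable]), doubled, type = "local")
  take_rev <- rev$score > fwd$score
  identity <- ifelse(take_rev, rev$identity, fwd$identity)
  aligned <- ifelse(take_rev, rev$aligned, fwd$aligned)
  out$identity[usable] <- identity
  out$aligned[usable] <- as.integer(aligned)
  out$strand[usable] <- ifelse(take_rev, "-", "+")
  out$hit[usable] <- identity >= min_identity & aligned >= min_aligned
  out
}
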