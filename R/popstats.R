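#' Multiple alignment of monomers by consensus-anchored star alignment
#'
#' Each monomer is pairwise-aligned globally to an anchor (the consensus if
#' given, otherwise the longest input sequence) and the pairwise alignments
#' are merged column-wise: insertions relative to the same anchor position
#' are padded to a common width. Removing gaps from any row recovers the
#' input sequence exactly.
#'
#' @param sequences Character vector of DNA sequences (>= 1).
#' @param consensus Optional `sat_consensus` or DNA string used as anchor;
#'   the anchor itself is not returned.
#' @return Character vector of gapped rows, all the same width, in input
#'   order (named after `names(sequences)` if present).
#' @export
align_monomers <- function(sequences, consensus = NULL) {
  if (length(sequences) == 0L) stop_param("cannot align zero sequences")
  assert_dna(sequences)
  if (length(sequences) == 1L) return(sequences)
  anchor <- if (is.null(consensus)) {
    sequences[order(-nchar(sequences), sequences)][1]
  } else {
    consensus_sequence(consensus)
  }
  La <- nchar(anchor)
  aln <- align_many(sequences, anchor, type = "global")

  # For each row, per anchor slot j in 0..La: the insertion string occurring
  # after j anchor characters, and the row character aligned to anchor
  # position j (or "-").
  parsed <- purrr::map2(aln$pattern, aln$subject, function(gp, gs) {
    p <- strsplit(gp, "", fixed = TRUE)[[1]]
    s <- strsplit(gs, "", fixed = TRUE)[[1]]
    apos <- cumsum(s != "-")          # anchor chars consumed at each column
    ins <- character(La + 1L)
    chr <- rep("-", La)
    for (k in seq_along(p)) {
      if (s[k] == "-") {
        ins[apos[k] + 1L] <- paste0(ins[apos[k] + 1L], p[k])
      } else {
        chr[apos[k]] <- p[k]
      }
    }
    list(ins = ins, chr = chr)
  })
  maxins <- purrr::reduce(purrr::map(parsed, ~ nchar(.x$ins)), pmax)
  rows <- vapply(parsed, function(pr) {
    pieces <- character(0)
    for (j in 0:La) {
      pad <- paste0(pr$ins[j + 1L],
                    strrep("-", maxins[j + 1L] - nchar(pr$ins[j + 1L])))
      pieces <- c(pieces, pad, if (j < La) pr$chr[j + 1L] else "")
    }
    paste(pieces, collapse = "")
  }, character(1))
  names(rows) <- names(sequences)
  rows
}

#' Unbiased haplotype diversity
#'
#' Nei's unbiased estimator `Hd = n/(n-1) * (1 - sum(p_i^2))`, the form used
#' by DnaSP: the probability that two sequences sampled without replacement
#' are different haplotypes.
#'
#' @param counts Integer vector of haplotype counts (each >= 1).
#' @return Haplotype diversity in `[0, 1]`.
#' @export
#' @examples
#' haplotype_diversity(c(2, 1))      # 2/3
#' haplotype_diversity(rep(1, 8))    # 1
haplotype_diversity <- function(counts) {
  if (any(counts < 1)) stop_param("haplotype counts must all be >= 1")
  n <- sum(counts)
  if (n < 2) {
    abort("haplotype diversity is undefined for fewer than 2 sequences",
          class = c("satlib_undefined_error", "satlib_error"))
  }
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Nucleotide diversity from an alignment of haplotypes
#'
#' Average per-site pairwise difference,
#' `pi = sum_{i<j} n_i n_j (d_ij / L_ij) / C(n, 2)`,
#' over all pairs of sequences (haplotypes weighted by their counts).
#' Under `indel_policy = "gap_as_event"` (default, reflecting analyses that
#' consider indels) each maximal gap run present in exactly one sequence of a
#' pair counts as one difference and each of its columns counts toward the
#' compared length; under `"complete_deletion"` every column containing a gap
#' in any row of the alignment is excluded. Columns where either sequence has
#' N are never compared.
#'
#' @param alignment Character vector of equal-length gapped rows.
#' @param counts Integer vector of per-row haplotype counts.
#' @param indel_policy `"gap_as_event"` or `"complete_deletion"`.
#' @return Nucleotide diversity (>= 0).
#' @export
nucleotide_diversity <- function(alignment, counts = rep(1L, length(alignment)),
                                 indel_policy = c("gap_as_event",
                                                  "complete_deletion")) {
  indel_policy <- match.arg(indel_policy)
  if (length(alignment) != length(counts)) {
    stop_param("alignment and counts must be parallel")
  }
  if (length(unique(nchar(alignment))) != 1L) {
    stop_param("alignment rows must all have the same length")
  }
  n <- sum(counts)
  if (n < 2) {
    abort("nucleotide diversity is undefined for fewer than 2 sequences",
          class = c("satlib_undefined_error", "satlib_error"))
  }
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  if (indel_policy == "complete_deletion") {
    keep <- colSums(mat == "-") == 0L
    if (!any(keep)) {
      stop_data("no gap-free columns remain under complete deletion")
    }
    mat <- mat[, keep, drop = FALSE]
  }
  k <- nrow(mat)
  if (k == 1L) return(0)
  total <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pd <- pair_diff(mat[i, ], mat[j, ], count_gap_events = (indel_policy == "gap_as_event"))
      if (pd$length > 0) total <- total + counts[i] * counts[j] * pd$diff / pd$length
    }
  }
  total / (n * (n - 1) / 2)
}

# Differences and compared length for one pair of gapped rows. Mismatches
# require both symbols in {A,C,G,T}; columns with N in either row are removed
# from both the difference and length tallies. When count_gap_events, each
# maximal gap run present in exactly one row adds one difference and its
# columns count toward the length; otherwise gap-containing columns are
# skipped entirely (pairwise deletion).
pair_diff <- function(a, b, count_gap_events = TRUE) {
  has_n <- a == "N" | b == "N"
  a <- a[!has_n]; b <- b[!has_n]
  ga <- a == "-"; gb <- b == "-"
  both_base <- !ga & !gb
  diff <- sum(a[both_base] != b[both_base])
  len <- sum(both_base)
  if (count_gap_events) {
    one_gap <- xor(ga, gb)
    r <- rle(ifelse(ga & !gb, "a", ifelse(gb & !ga, "b", ".")))
    diff <- diff + sum(r$values != ".")
    len <- len + sum(one_gap)
  }
  list(diff = diff, length = len)
}

#' Per-column base frequencies and information content
#'
#' Count-weighted base frequencies per alignment column plus Shannon entropy
#' and sequence-logo information content `R = 2 - H` (bits), computed on
#' non-gap bases. N is treated as missing. Columns that are entirely gaps get
#' `NA` entropy and information.
#'
#' @param alignment Character vector of equal-length gapped rows.
#' @param counts Per-row haplotype counts (default 1 each).
#' @return Tibble of class `sat_logo` with columns `column`, `f_A`, `f_C`,
#'   `f_G`, `f_T`, `f_gap`, `H_bits`, `R_bits`.
#' @export
logo_matrix <- function(alignment, counts = rep(1L, length(alignment))) {
  if (length(alignment) == 0L) stop_param("alignment must be non-empty")
  if (length(unique(nchar(alignment))) != 1L) {
    stop_param("alignment rows must all have the same length")
  }
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  w <- as.numeric(counts)
  cols <- purrr::map(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    use <- col != "N"
    tot <- sum(w[use])
    freq <- vapply(c(DNA_BASES, "-"), function(bb) {
      if (tot > 0) sum(w[use][col[use] == bb]) / tot else NA_real_
    }, numeric(1))
    base_tot <- sum(freq[DNA_BASES])
    if (is.na(base_tot) || base_tot <= 0) {
      H <- NA_real_
    } else {
      p <- freq[DNA_BASES] / base_tot
      p <- p[p > 0]
      H <- -sum(p * log2(p))
    }
    c(freq, H_bits = H, R_bits = if (is.na(H)) NA_real_ else 2 - H)
  })
  out <- as_tibble(do.call(rbind, cols))
  names(out) <- c("f_A", "f_C", "f_G", "f_T", "f_gap", "H_bits", "R_bits")
  out <- dplyr::mutate(out, column = dplyr::row_number(), .before = 1)
  class(out) <- c("sat_logo", class(out))
  out
}

#' Summarize diversity per species and origin
#'
#' Produces one row per (species, origin): sample size N (sum of haplotype
#' counts), ungapped monomer size range, number of haplotypes, unbiased
#' haplotype diversity and nucleotide diversity — the standard per-species
#' satellite variation summary.
#'
#' @param haplotypes A `sat_haplotypes` tibble (see [tally_haplotypes()]),
#'   or any tibble with `sequence`, `count`, `species`, `origin`.
#' @param consensus Optional alignment anchor passed to [align_monomers()].
#' @param indel_policy Passed to [nucleotide_diversity()].
#' @return Tibble of class `sat_diversity` with columns `species`, `origin`,
#'   `N`, `size_min`, `size_max`, `Hap`, `Hd`, `pi`. `Hd`/`pi` are `NA` when
#'   N < 2.
#' @export
summarize_diversity <- function(haplotypes, consensus = NULL,
                                indel_policy = "gap_as_event") {
  if (nrow(haplotypes) == 0L) {
    stop_data("cannot summarize an empty haplotype table")
  }
  out <- haplotypes |>
    dplyr::group_by(.data$species, .data$origin) |>
    dplyr::group_modify(function(g, key) {
      lens <- nchar(g$sequence)
      n <- sum(g$count)
      if (n >= 2) {
        hd <- haplotype_diversity(g$count)
        alnr <- align_monomers(g$sequence, consensus = consensus)
        pi <- nucleotide_diversity(alnr, g$count, indel_policy = indel_policy)
      } else {
        hd <- NA_real_; pi <- NA_real_
      }
      tibble(N = as.integer(n), size_min = min(lens), size_max = max(lens),
             Hap = nrow(g), Hd = hd, pi = pi)
    }) |>
    dplyr::ungroup()
  class(out) <- c("sat_diversity", class(out))
  out
}

#' Format a diversity table at report precision
#'
#' Truncates `Hd` and `pi` at the given number of decimals, the convention of
#' published satellite variation tables (see [trunc_digits()]).
#'
#' @param stats A `sat_diversity` tibble.
#' @param digits Decimals kept (default 2).
#' @return Tibble with truncated `Hd` and `pi`.
#' @export
format_diversity <- function(stats, digits = 2) {
  dplyr::mutate(stats, dplyr::across(dplyr::any_of(c("Hd", "pi")),
                                     ~ trunc_digits(.x, digits)))
}
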