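# Internal wrappers around Biostrings::pairwiseAlignment with the package-wide
# scoring scheme: match +1, mismatch -1, gap open -2, gap extend -1 per base.
# N never scores as a match (N-N is a mismatch too), so ambiguous bases cannot
# inflate identity.

sat_sub_matrix <- function() {
  b <- c(DNA_BASES, "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}

# Vectorised alignment of many patterns against one subject. Returns the
# gapped pattern/subject strings plus score; identity and aligned length are
# computed from the gapped strings so gap columns count as columns and N
# columns never count as matches.
align_many <- function(patterns, subject, type = c("global", "local")) {
  type <- match.arg(type)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns),
    Biostrings::DNAString(subject),
    type = type,
    substitutionMatrix = sat_sub_matrix(),
    gapOpening = 2, gapExtension = 1
  )
  gp <- as.character(Biostrings::pattern(aln))
  gs <- as.character(Biostrings::subject(aln))
  stats <- purrr::map2(gp, gs, gapped_identity)
  tibble(
    pattern = gp,
    subject = gs,
    score = Biostrings::score(aln),
    identity = purrr::map_dbl(stats, "identity"),
    aligned = purrr::map_int(stats, "columns"),
    pattern_start = Biostrings::start(Biostrings::pattern(aln)),
    pattern_end = Biostrings::end(Biostrings::pattern(aln)),
    subject_start = Biostrings::start(Biostrings::subject(aln)),
    subject_end = Biostrings::end(Biostrings::subject(aln))
  )
}

# identity = matches / alignment columns; gaps count as columns, N never
# matches anything.
gapped_identity <- function(gp, gs) {
  a <- strsplit(gp, "", fixed = TRUE)[[1]]
  b <- strsplit(gs, "", fixed = TRUE)[[1]]
  cols <- length(a)
  matches <- sum(a == b & a %in% DNA_BASES)
  list(identity = if (cols > 0) matches / cols else 0, columns = as.integer(cols))
}

# Global identity between two sequences under the package scoring scheme.
global_identity <- function(a, b) {
  align_many(a, b, type = "global")$identity[1]
}
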