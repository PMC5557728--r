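#' Define a satellite consensus reference
#'
#' @param name Family name; by satellite nomenclature the trailing number is
#'   the unit length (e.g. a 177-bp family is `<Genus>Sat01-177`).
#' @param sequence Consensus monomer sequence; its length is the unit length.
#' @return A list of class `sat_consensus` with `name`, `unit_length`,
#'   `sequence`.
#' @export
sat_consensus <- function(name, sequence) {
  assert_dna(sequence, what = "consensus")
  structure(
    list(name = name, unit_length = nchar(sequence), sequence = sequence),
    class = "sat_consensus"
  )
}

consensus_sequence <- function(x) {
  if (inherits(x, "sat_consensus")) x$sequence else {
    assert_dna(x, what = "consensus")
    x
  }
}

#' Read a consensus monomer from FASTA
#'
#' The first record is used; its name becomes the family name.
#'
#' @param path FASTA file path.
#' @return A `sat_consensus`.
#' @export
read_consensus_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop_data("consensus FASTA is empty", stage = "input")
  sat_consensus(sub("\\s.*$", "", names(x)[1]), as.character(x[[1]]))
}

#' Canonical rotation of monomers against a consensus
#'
#' A monomer cut out of a tandem array has an arbitrary phase; this rotates
#' each monomer so that its global alignment score against the consensus is
#' maximal, giving all monomers a common origin. Score ties are broken by the
#' lexicographically smallest rotated string (then smallest offset), so the
#' result is invariant to the phase of the input; the function is idempotent.
#'
#' @param monomers Character vector of DNA monomers.
#' @param consensus A `sat_consensus` or DNA string.
#' @return Character vector of canonically rotated monomers.
#' @export
canonical_rotation <- function(monomers, consensus) {
  cons <- consensus_sequence(consensus)
  assert_dna(monomers, what = "monomer")
  uniq <- unique(monomers)
  canon <- vapply(uniq, function(m) {
    rots <- all_rotations(m)
    sc <- align_many(rots, cons, type = "global")$score
    best <- which(sc == max(sc))
    rots[best[order(rots[best], best)][1]]
  }, character(1), USE.NAMES = FALSE)
  canon[match(monomers, uniq)]
}

#' Extract full-length monomers from merged reads
#'
#' Aligns each merged read locally against a tiled (repeated) consensus so
#' the circular coordinate system of the tandem repeat is respected, cuts the
#' read at consecutive consensus origins, canonicalizes each cut segment's
#' rotation, and keeps segments passing the identity and length filters.
#' Reads spanning less than one full unit yield nothing. Both strands are
#' considered.
#'
#' @param merged Tibble from [merge_pairs()] (columns `id`, `sequence`,
#'   `merged`), or a character vector of sequences.
#' @param consensus A `sat_consensus` or DNA string.
#' @param min_identity Minimum global identity of a segment to the consensus
#'   (default 0.60, permissive so diverged relictual variants are kept).
#' @param length_tol Allowed fractional deviation of segment length from the
#'   unit length (default 0.10, matching observed 166-186 bp monomers for a
#'   177 bp unit).
#' @param species,origin Annotations carried onto the monomers.
#' @return Tibble with columns `sequence`, `read_id`, `species`, `origin`,
#'   `length`.
#' @export
extract_monomers <- function(merged, consensus, min_identity = 0.60,
                             length_tol = 0.10, species = NA_character_,
                             origin = "illumina") {
  cons <- consensus_sequence(consensus)
  unit <- nchar(cons)
  if (is.character(merged)) {
    merged <- tibble(id = sprintf("m%06d", seq_along(merged)),
                     sequence = merged, merged = TRUE)
  }
  merged <- merged[!is.na(merged$sequence) & merged$merged %||% TRUE, , drop = FALSE]
  empty <- tibble(sequence = character(), read_id = character(),
                  species = character(), origin = character(), length = integer())
  if (nrow(merged) == 0L) return(empty)

  segs <- purrr::map2(merged$sequence, merged$id, function(q, id) {
    cut_at_origins(q, cons, unit)
  })
  n_per <- lengths(segs)
  if (sum(n_per) == 0L) return(empty)
  out <- tibble(
    sequence = unlist(segs, use.names = FALSE),
    read_id = rep(merged$id, n_per)
  )
  out$sequence <- canonical_rotation(out$sequence, cons)
  out$length <- nchar(out$sequence)

  lo <- unit * (1 - length_tol); hi <- unit * (1 + length_tol)
  keep_len <- out$length >= lo & out$length <= hi
  out <- out[keep_len, , drop = FALSE]
  if (nrow(out) > 0L) {
    uniq <- unique(out$sequence)
    idy <- align_many(uniq, cons, type = "global")$identity
    out <- out[idy[match(out$sequence, uniq)] >= min_identity, , drop = FALSE]
  }
  out$species <- species
  out$origin <- origin
  out[, c("sequence", "read_id", "species", "origin", "length")]
}

# Cut one merged read at consecutive consensus origins. Returns character
# vector of segments (possibly empty). Uses the better strand.
cut_at_origins <- function(q, cons, unit) {
  reps <- ceiling(nchar(q) / unit) + 2L
  tiled <- strrep(cons, reps)
  cands <- c(q, revcomp(q))
  aln <- align_many(cands, tiled, type = "local")
  a <- aln[which.max(aln$score), ]
  qseq <- cands[which.max(aln$score)]

  p <- strsplit(a$pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(a$subject, "", fixed = TRUE)[[1]]
  # read/subject coordinate at each alignment column
  rpos <- a$pattern_start - 1L + cumsum(p != "-")
  spos <- a$subject_start - 1L + cumsum(s != "-")
  # origins are subject positions == 1 (mod unit); a full unit needs origin o
  # and o+unit both inside [subject_start, subject_end + 1]
  o_first <- a$subject_start + ((1L - a$subject_start) %% unit)
  origins <- seq(o_first, a$subject_end + 1L, by = unit)
  if (length(origins) < 2L) return(character(0))
  # read coordinate where each origin starts: first column whose subject
  # coordinate reaches the origin (handles deletions at the boundary)
  rd <- vapply(origins, function(o) {
    if (o == a$subject_end + 1L) return(a$pattern_end + 1L)
    j <- which(spos >= o & s != "-")[1]
    if (is.na(j)) return(NA_integer_)
    as.integer(rpos[j] + (p[j] == "-"))
  }, integer(1))
  segs <- character(0)
  for (k in seq_len(length(origins) - 1L)) {
    if (is.na(rd[k]) || is.na(rd[k + 1L]) || rd[k + 1L] <= rd[k]) next
    segs <- c(segs, substr(qseq, rd[k], rd[k + 1L] - 1L))
  }
  segs
}

#' Collapse monomers to haplotypes and filter singletons
#'
#' Identical sequences are collapsed to one haplotype per species/origin with
#' a count. With `drop_singletons = TRUE`, haplotypes observed exactly once
#' among Illumina-derived monomers are removed to suppress sequencing-error
#' artifacts; PCR-derived clones are kept regardless (Sanger clones are few
#' and mostly unique by design).
#'
#' @param monomers Tibble from [extract_monomers()].
#' @param drop_singletons Apply the singleton filter to Illumina monomers.
#' @return Tibble of class `sat_haplotypes` with columns `haplotype`,
#'   `sequence`, `count`, `species`, `origin`, `length`.
#' @export
tally_haplotypes <- function(monomers, drop_singletons = TRUE) {
  out <- monomers |>
    dplyr::count(.data$species, .data$origin, .data$sequence, name = "count") |>
    dplyr::arrange(.data$species, .data$origin, dplyr::desc(.data$count),
                   .data$sequence)
  if (drop_singletons) {
    out <- dplyr::filter(out, .data$count >= 2L | .data$origin != "illumina")
  }
  out <- out |>
    dplyr::group_by(.data$species, .data$origin) |>
    dplyr::mutate(haplotype = sprintf("%s_%s_h%03d",
                                      .data$species, .data$origin,
                                      dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(length = nchar(.data$sequence)) |>
    dplyr::select("haplotype", "sequence", "count", "species", "origin", "length")
  class(out) <- c("sat_haplotypes", class(out))
  out
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' In-silico PCR with degenerate primers
#'
#' Finds forward-primer sites on the plus strand and reverse-primer sites on
#' the minus strand under IUPAC degenerate matching (R = A/G, Y = C/T, N =
#' any), allowing up to `max_mismatches` mismatches per site, and reports all
#' products whose length lies in `product_range`. On a tandem array the
#' products form a ladder at unit-length spacing.
#'
#' @param template DNA string (e.g. a tandem array or genome fragment).
#' @param forward,reverse Primer sequences over the IUPAC alphabet (reverse
#'   given 5'->3' as synthesised).
#' @param max_mismatches Maximum mismatches tolerated per primer site.
#' @param product_range Length range `c(min, max)` of reported products.
#' @return Tibble with columns `start`, `end`, `length`, sorted by length.
#' @export
in_silico_pcr <- function(template, forward, reverse, max_mismatches = 0L,
                          product_range = c(50L, 2000L)) {
  assert_dna(template, what = "template")
  for (p in c(forward, reverse)) {
    if (nchar(p) == 0L) stop_param("primers must be non-empty")
    bad <- setdiff(strsplit(p, "", fixed = TRUE)[[1]], names(IUPAC_SETS))
    if (length(bad)) {
      stop_param(sprintf("primer contains non-IUPAC symbol(s): %s",
                         paste(bad, collapse = ", ")))
    }
  }
  subj <- Biostrings::DNAString(template)
  fwd_sites <- Biostrings::matchPattern(
    Biostrings::DNAString(forward), subj,
    max.mismatch = max_mismatches, fixed = FALSE
  )
  rev_sites <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse)), subj,
    max.mismatch = max_mismatches, fixed = FALSE
  )
  if (length(fwd_sites) == 0L || length(rev_sites) == 0L) {
    return(tibble(start = integer(), end = integer(), length = integer()))
  }
  grid <- tidyr::expand_grid(start = Biostrings::start(fwd_sites),
                             end = Biostrings::end(rev_sites)) |>
    dplyr::mutate(length = .data$end - .data$start + 1L) |>
    dplyr::filter(.data$length >= product_range[1],
                  .data$length <= product_range[2]) |>
    dplyr::arrange(.data$length, .data$start)
  grid
}
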