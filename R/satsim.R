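#' Simulate an ancestral satellite DNA library
#'
#' Generates a set of related monomer haplotypes emulating the satellite
#' "library" shared by related species: a single root monomer is drawn
#' uniformly over `{A,C,G,T}` and every other haplotype is derived from it by
#' i.i.d. per-site substitution at rate `divergence`.
#'
#' @param n_haplotypes Number of haplotypes in the library (>= 1).
#' @param unit_length Monomer unit length in nucleotides (>= 10); satellite
#'   families in the target system are ~177 bp.
#' @param divergence Expected per-site substitution proportion between the
#'   root and each derived haplotype, in `[0, 0.5]`.
#' @param seed Integer seed; identical seed and parameters give an identical
#'   library.
#' @return A tibble of class `sat_library` with columns `id` and `sequence`,
#'   and attributes `unit_length` and `divergence`. Row 1 is the root.
#' @export
#' @examples
#' simulate_library(n_haplotypes = 3, unit_length = 60, divergence = 0.05, seed = 1)
simulate_library <- function(n_haplotypes, unit_length = 177, divergence = 0.02,
                             seed = 1L) {
  if (n_haplotypes < 1) stop_param("n_haplotypes must be >= 1")
  if (unit_length < 10) stop_param("unit_length must be >= 10")
  if (divergence < 0 || divergence > 0.5) stop_param("divergence must be in [0, 0.5]")
  withr::with_seed(seed, {
    root <- paste(sample(DNA_BASES, unit_length, replace = TRUE), collapse = "")
    seqs <- c(root, vapply(seq_len(n_haplotypes - 1L), function(i) {
      mutate_sites(root, divergence)
    }, character(1)))
  })
  out <- tibble(
    id = sprintf("hap%02d", seq_len(n_haplotypes)),
    sequence = seqs[seq_len(n_haplotypes)]
  )
  attr(out, "unit_length") <- as.integer(unit_length)
  attr(out, "divergence") <- divergence
  class(out) <- c("sat_library", class(out))
  out
}

# i.i.d. per-site substitution: each selected site is replaced by one of the
# three other bases, uniformly.
mutate_sites <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(s)) < rate
  if (any(hit)) {
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                     character(1), USE.NAMES = FALSE)
  }
  paste(s, collapse = "")
}

# 1-9 nt insertion or deletion at a random position, with per-monomer
# probability `rate`.
maybe_indel <- function(seq, rate) {
  if (rate <= 0 || runif(1) >= rate) return(seq)
  L <- nchar(seq)
  k <- sample(1:9, 1)
  if (runif(1) < 0.5 && L > k + 1) {  # deletion
    pos <- sample(L - k, 1)
    paste0(substr(seq, 1, pos - 1), substr(seq, pos + k, L))
  } else {                            # insertion
    pos <- sample(L + 1, 1) - 1L
    ins <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
    paste0(substr(seq, 1, pos), ins, substr(seq, pos + 1, L))
  }
}

#' Define a species amplification profile
#'
#' Bundles the simulator parameters for one species: how strongly each
#' ancestral haplotype was amplified in that genome, how many monomer copies
#' the genome carries, and the post-amplification substitution/indel rates
#' (low rates emulate efficient homogenization; high rates a relictual,
#' diverged satellite).
#'
#' @param species Species name.
#' @param weights Non-negative amplification weight per ancestral haplotype;
#'   at least one must be positive. Normalised internally to sum to 1.
#' @param copies Total monomer copies in the simulated genome (>= 0).
#' @param mutation_rate Per-site substitution probability applied to each
#'   amplified copy.
#' @param indel_rate Per-monomer probability of a single 1-9 nt indel.
#' @return A list of class `species_profile`.
#' @export
species_profile <- function(species, weights, copies,
                            mutation_rate = 0, indel_rate = 0) {
  if (!is.numeric(weights) || any(weights < 0)) {
    stop_param("weights must be non-negative numbers")
  }
  if (sum(weights) <= 0) stop_param("at least one amplification weight must be > 0")
  if (copies < 0) stop_param("copies must be >= 0")
  rates <- c(mutation_rate, indel_rate)
  if (any(rates < 0 | rates > 1)) stop_param("rates must lie in [0, 1]")
  structure(
    list(
      species = species,
      weights = weights / sum(weights),
      copies = as.integer(copies),
      mutation_rate = mutation_rate,
      indel_rate = indel_rate
    ),
    class = "species_profile"
  )
}

#' Amplify a species monomer pool from the ancestral library
#'
#' Draws `copies` monomers from the ancestral haplotypes according to the
#' profile's amplification weights, then applies per-copy substitution and
#' indel mutation. Every copy keeps its true ancestral label so downstream
#' recovery can be scored against ground truth.
#'
#' @param library A `sat_library` (see [simulate_library()]).
#' @param profile A `species_profile`; `weights` must have one entry per
#'   library haplotype.
#' @param seed Integer seed.
#' @return Tibble with columns `monomer_id`, `sequence`, `ancestral_id`,
#'   `species`.
#' @export
amplify_species <- function(library, profile, seed = 1L) {
  if (length(profile$weights) != nrow(library)) {
    stop_param("profile weights must have one entry per library haplotype")
  }
  n <- profile$copies
  if (n == 0L) {
    return(tibble(monomer_id = character(), sequence = character(),
                  ancestral_id = character(), species = character()))
  }
  withr::with_seed(seed, {
    picks <- sample.int(nrow(library), n, replace = TRUE, prob = profile$weights)
    seqs <- library$sequence[picks]
    seqs <- vapply(seqs, mutate_sites, character(1), rate = profile$mutation_rate,
                   USE.NAMES = FALSE)
    seqs <- vapply(seqs, maybe_indel, character(1), rate = profile$indel_rate,
                   USE.NAMES = FALSE)
  })
  tibble(
    monomer_id = sprintf("%s_m%05d", profile$species, seq_len(n)),
    sequence = seqs,
    ancestral_id = library$id[picks],
    species = profile$species
  )
}

#' Concatenate a monomer pool into a tandem array
#'
#' Satellite monomers sit head-to-tail in long arrays; this concatenates the
#' whole pool in a seeded shuffled order.
#'
#' @param pool Tibble from [amplify_species()] (columns `monomer_id`,
#'   `sequence`, ...), or a character vector of monomers.
#' @param seed Integer seed controlling the shuffle.
#' @return A list of class `sat_array` with elements `sequence` (the array)
#'   and `truth` (tibble: `monomer_id`, `ancestral_id`, `species`, `offset`,
#'   `length`; `offset` is the 1-based array start of each monomer).
#' @export
build_tandem_array <- function(pool, seed = 1L) {
  if (is.character(pool)) {
    pool <- tibble(monomer_id = sprintf("m%05d", seq_along(pool)),
                   sequence = pool,
                   ancestral_id = NA_character_, species = NA_character_)
  }
  if (nrow(pool) == 0L) stop_param("cannot build a tandem array from an empty pool")
  ord <- withr::with_seed(seed, sample.int(nrow(pool)))
  shuffled <- pool[ord, , drop = FALSE]
  lens <- nchar(shuffled$sequence)
  offsets <- cumsum(c(1L, lens[-length(lens)]))
  structure(
    list(
      sequence = paste(shuffled$sequence, collapse = ""),
      truth = tibble(
        monomer_id = shuffled$monomer_id,
        ancestral_id = shuffled$ancestral_id,
        species = shuffled$species,
        offset = offsets,
        length = lens
      )
    ),
    class = "sat_array"
  )
}

#' Simulate paired-end reads from a tandem array
#'
#' Fragments are sampled uniformly along the array treated as circular
#' (wrap-around), mimicking arrays much longer than the simulated one, so
#' edge monomers are not under-covered. Mate 1 is the fragment prefix; mate 2
#' the reverse complement of the fragment suffix. Sequencing errors are
#' i.i.d. substitutions; read-level indels are not simulated (monomer-level
#' indels belong in [amplify_species()]).
#'
#' @param array A `sat_array` or a DNA string.
#' @param n_pairs Number of read pairs (>= 0).
#' @param read_length Read length for both mates.
#' @param frag_mean,frag_sd Fragment length distribution (normal, rounded,
#'   clamped to `[read_length, array length]`).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed; identical inputs give byte-identical reads.
#' @param quality_char Constant Phred+33 quality character (default `"F"`,
#'   Q37; the pipeline uses qualities only to resolve merge mismatches).
#' @return Tibble with columns `id`, `mate1`, `qual1`, `mate2`, `qual2`.
#' @export
generate_reads <- function(array, n_pairs, read_length = 250, frag_mean = 400,
                           frag_sd = 40, error_rate = 0, seed = 1L,
                           quality_char = "F") {
  seqstr <- if (inherits(array, "sat_array")) array$sequence else array
  assert_dna(seqstr, what = "array")
  L <- nchar(seqstr)
  if (read_length > frag_mean) stop_param("read_length must be <= frag_mean")
  if (L < frag_mean) stop_param("array length must be >= frag_mean")
  if (n_pairs < 0) stop_param("n_pairs must be >= 0")
  if (n_pairs == 0L) {
    return(tibble(id = character(), mate1 = character(), qual1 = character(),
                  mate2 = character(), qual2 = character()))
  }
  doubled <- paste0(seqstr, seqstr)  # circular coordinates
  withr::with_seed(seed, {
    frag_len <- pmin(pmax(as.integer(round(rnorm(n_pairs, frag_mean, frag_sd))),
                          read_length), L)
    start <- sample.int(L, n_pairs, replace = TRUE)
    frags <- substring(doubled, start, start + frag_len - 1L)
    m1 <- substr(frags, 1L, read_length)
    m2 <- revcomp(substring(frags, frag_len - read_length + 1L, frag_len))
    if (error_rate > 0) {
      m1 <- vapply(m1, mutate_sites, character(1), rate = error_rate,
                   USE.NAMES = FALSE)
      m2 <- vapply(m2, mutate_sites, character(1), rate = error_rate,
                   USE.NAMES = FALSE)
    }
  })
  qual <- strrep(quality_char, read_length)
  tibble(
    id = sprintf("read%06d", seq_len(n_pairs)),
    mate1 = m1, qual1 = qual,
    mate2 = m2, qual2 = qual
  )
}

#' Write paired reads as FASTQ files
#'
#' @param reads Tibble with columns `id`, `mate1`, `qual1`, `mate2`, `qual2`.
#' @param prefix Output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written (`.fastq.gz` when `gzip = TRUE`).
#' @param gzip Compress output.
#' @return Invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  for (i in 1:2) {
    s <- Biostrings::DNAStringSet(setNames(reads[[c("mate1", "mate2")[i]]],
                                           reads$id))
    q <- Biostrings::BStringSet(reads[[c("qual1", "qual2")[i]]])
    Biostrings::writeXStringSet(s, paths[i], format = "fastq", qualities = q,
                                compress = gzip)
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1,r2 Paths to mate-1 and mate-2 FASTQ (optionally gzipped).
#' @return Tibble with columns `id`, `mate1`, `qual1`, `mate2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  x1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  x2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(x1) != length(x2)) {
    stop_data("mate files contain different numbers of reads", stage = "readprep")
  }
  tibble(
    id = sub("\\s.*$", "", names(x1)),
    mate1 = as.character(x1),
    qual1 = as.character(S4Vectors::mcols(x1)$qualities),
    mate2 = as.character(x2),
    qual2 = as.character(S4Vectors::mcols(x2)$qualities)
  )
}
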