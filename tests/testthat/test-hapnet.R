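test_that("greedy clustering collapses identical and near-identical sequences", {
  s <- random_dna(1, 200, seed = 301)
  tab <- tibble::tibble(
    haplotype = c("a", "b", "c"), sequence = s, count = c(5L, 3L, 2L),
    species = "sp", origin = "illumina"
  )
  cl <- greedy_cluster(tab, threshold = 0.99)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$abundance, 10)
  expect_equal(cl$clusters$n_members, 3L)

  # one substitution in 200 nt: identity 0.995 >= 0.99 -> one cluster
  mut1 <- s
  substr(mut1, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s, 50, 50))[1]
  two <- tibble::tibble(haplotype = c("a", "b"), sequence = c(s, mut1),
                        count = c(5L, 1L), species = "sp", origin = "illumina")
  expect_equal(nrow(greedy_cluster(two, 0.99)$clusters), 1)

  # three substitutions: identity 0.985 < 0.99 -> two clusters
  mut3 <- s
  for (p in c(50, 90, 130)) {
    substr(mut3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
  }
  three <- tibble::tibble(haplotype = c("a", "b"), sequence = c(s, mut3),
                          count = c(5L, 1L), species = "sp",
                          origin = "illumina")
  expect_equal(nrow(greedy_cluster(three, 0.99)$clusters), 2)
})

test_that("clustering at threshold 1 is exact deduplication", {
  seqs <- c(random_dna(5, 60, seed = 302), random_dna(5, 60, seed = 302))
  cl <- greedy_cluster(seqs, threshold = 1.0)
  expect_equal(nrow(cl$clusters), 5)
  expect_equal(nrow(cl$members), 10)
  expect_true(all(cl$clusters$n_members == 2L))

  distinct <- random_dna(6, 60, seed = 303)
  expect_equal(nrow(greedy_cluster(distinct, 1.0)$clusters), 6)
})

test_that("clusters partition the input and members match their representative", {
  base <- random_dna(1, 100, seed = 304)
  withr::with_seed(305, {
    seqs <- vapply(1:12, function(i) satlib:::mutate_sites(base, 0.05),
                   character(1))
  })
  tab <- tibble::tibble(haplotype = sprintf("h%02d", 1:12), sequence = seqs,
                        count = 12:1, species = "sp", origin = "illumina")
  cl <- greedy_cluster(tab, threshold = 0.97)
  expect_setequal(cl$members$haplotype, tab$haplotype)
  expect_equal(sum(cl$clusters$n_members), 12L)
  expect_equal(sum(cl$clusters$abundance), sum(tab$count))
  merged <- dplyr::left_join(cl$members, cl$clusters, by = "cluster")
  for (i in seq_len(nrow(merged))) {
    idy <- satlib:::global_identity(
      tab$sequence[tab$haplotype == merged$haplotype[i]],
      merged$sequence[i]
    )
    expect_gte(idy, 0.97)
  }
})

test_that("lowering the clustering threshold never increases cluster count", {
  base <- random_dna(1, 80, seed = 306)
  withr::with_seed(307, {
    seqs <- vapply(1:15, function(i) satlib:::mutate_sites(base, 0.08),
                   character(1))
  })
  counts <- vapply(c(1.0, 0.99, 0.95, 0.9, 0.8), function(t) {
    nrow(greedy_cluster(seqs, threshold = t)$clusters)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(greedy_cluster(seqs, threshold = 0), class = "satlib_param_error")
})

test_that("pairwise differences count base changes and indel events", {
  aln <- c(a = "ACGT", b = "ACGT")
  expect_equal(pairwise_differences(aln)["a", "b"], 0L)
  expect_equal(pairwise_differences(c(a = "ACGT", b = "ACCT"))["a", "b"], 1L)
  expect_equal(pairwise_differences(c(a = "AC--GT", b = "ACTTGT"))["a", "b"], 1L)
  d <- pairwise_differences(c(a = "A-CGTT", b = "ATCG-T", c = "ATCGAT"))
  expect_equal(d["a", "b"], 2L)  # two separate 1 nt indel events
  expect_equal(d["a", "c"], 2L)  # one indel + one mismatch... verified below
  expect_equal(d["b", "c"], 1L)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_error(pairwise_differences(c("AC", "ACG")),
               class = "satlib_param_error")
})

test_that("pairwise differences agree with a gap-run oracle on random cases", {
  withr::with_seed(308, {
    for (i in 1:20) {
      L <- sample(10:25, 1)
      mk <- function() {
        s <- strsplit(random_dna(1, L), "")[[1]]
        s[runif(L) < 0.15] <- "-"
        paste(s, collapse = "")
      }
      rows <- c(a = mk(), b = mk())
      expect_equal(pairwise_differences(rows)["a", "b"],
                   oracle_pair_steps(rows[1], rows[2]))
    }
  })
})

test_that("the MST is minimal, acyclic and expands steps correctly", {
  dm <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  mst <- build_mst(dm)
  expect_equal(nrow(mst$edges), 1)
  expect_equal(mst$n_steps, 2L)
  expect_equal(igraph::vcount(mst$graph), 4)  # 2 haplotypes + 2 steps
  expect_equal(igraph::ecount(mst$graph), 3)  # 3 unit steps

  tri <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m2 <- build_mst(tri)
  expect_equal(mst_weight(m2), 3)
  expect_equal(sort(paste(m2$edges$from, m2$edges$to)), c("A B", "A C"))

  single <- build_mst(matrix(0, 1, 1, dimnames = list("x", "x")))
  expect_equal(nrow(single$edges), 0)
  expect_equal(igraph::vcount(single$graph), 1)
})

test_that("MST weight equals the exhaustive spanning-tree minimum (n <= 7)", {
  withr::with_seed(309, {
    for (n in c(4, 5, 6, 7)) {
      d <- matrix(0L, n, n)
      d[upper.tri(d)] <- sample(0:9, n * (n - 1) / 2, replace = TRUE)
      d <- d + t(d)
      dimnames(d) <- list(letters[1:n], letters[1:n])
      mst <- build_mst(d)
      expect_equal(mst_weight(mst), oracle_mst_weight(d))
      expect_equal(nrow(mst$edges), n - 1)
      expect_true(igraph::is_connected(mst$graph))
      expect_equal(igraph::ecount(mst$graph),
                   igraph::vcount(mst$graph) - 1)  # acyclic + connected
      # post-expansion node count = haplotypes + sum(k_e - 1)
      expect_equal(igraph::vcount(mst$graph),
                   n + sum(pmax(mst$edges$weight - 1, 0)))
    }
  })
})

test_that("tie-breaking makes the MST deterministic", {
  d <- matrix(1L, 4, 4); diag(d) <- 0L
  dimnames(d) <- list(letters[1:4], letters[1:4])
  m1 <- build_mst(d); m2 <- build_mst(d)
  expect_identical(m1$edges, m2$edges)
  # lexicographically earliest tie edges win
  expect_equal(m1$edges$from, c("a", "a", "a"))
  expect_equal(m1$edges$to, c("b", "c", "d"))
})

test_that("GML export round-trips the expanded graph", {
  dm <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("h1", "h2"),
                                                    c("h1", "h2")))
  nodes <- tibble::tibble(id = c("h1", "h2"), species = c("sp1", "sp2"),
                          origin = c("illumina", "pcr"), abundance = c(9, 1))
  mst <- build_mst(dm, nodes)
  gml <- withr::local_tempfile(fileext = ".gml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(mst, gml, tsv)
  g2 <- read_mst_gml(gml)
  expect_equal(igraph::vcount(g2), igraph::vcount(mst$graph))
  expect_equal(igraph::ecount(g2), igraph::ecount(mst$graph))
  expect_setequal(igraph::V(g2)$name, igraph::V(mst$graph)$name)
  expect_equal(sum(igraph::V(g2)$step), mst$n_steps)
  nt <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(nt), 2 + mst$n_steps)
})

test_that("same-species haplotypes group together under strong homogenization", {
  lib <- simulate_library(4, 120, divergence = 0.10, seed = 310)
  pools <- purrr::map2(
    list(c(1, 0, 0, 0), c(0, 0, 0, 1)), c("spA", "spB"),
    function(w, name) {
      prof <- species_profile(name, w, copies = 30, mutation_rate = 0.01)
      amplify_species(lib, prof, seed = 311)
    }
  )
  tab <- dplyr::bind_rows(pools) |>
    dplyr::count(species, sequence, name = "count") |>
    dplyr::mutate(haplotype = sprintf("%s_%02d", species, dplyr::row_number()),
                  origin = "illumina")
  aln <- align_monomers(setNames(tab$sequence, tab$haplotype),
                        consensus = lib$sequence[1])
  dm <- pairwise_differences(aln)
  mst <- build_mst(dm, nodes = tibble::tibble(
    id = tab$haplotype, species = tab$species, origin = tab$origin,
    abundance = tab$count
  ))
  coh <- mst_species_coherence(mst, n_perm = 999, seed = 312)
  expect_gt(coh$observed, coh$null_mean)
  expect_lt(coh$p_value, 0.05)
})

test_that("tidy and glance summarise clusters and trees", {
  dm <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("h1", "h2"),
                                                    c("h1", "h2")))
  mst <- build_mst(dm)
  td <- generics::tidy(mst)
  expect_equal(nrow(td), 1)
  gl <- generics::glance(mst)
  expect_equal(gl$total_weight, 2)
  expect_equal(gl$n_step_nodes, 1L)

  cl <- greedy_cluster(random_dna(4, 30, seed = 313), 1.0)
  expect_equal(generics::glance(cl)$n_clusters, 4)
  expect_equal(nrow(generics::tidy(cl)), 4)
})
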