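#' Greedy identity clustering of haplotypes
#'
#' CD-HIT-style greedy incremental clustering: haplotypes are sorted by
#' abundance (descending), then length (descending), then sequence, and each
#' one joins the first existing cluster whose representative it matches at
#' `>= threshold` global identity (matches / alignment columns), otherwise it
#' founds a new cluster. Deterministic given the input table.
#'
#' @param haplotypes A `sat_haplotypes` tibble (columns `haplotype`,
#'   `sequence`, `count`, ...), or a character vector of sequences.
#' @param threshold Identity threshold in `(0, 1]` (0.99 reduces haplotype
#'   inflation from near-identical variants before network building).
#' @return A list of class `sat_clusters`: `members` (tibble mapping every
#'   haplotype to `cluster`) and `clusters` (tibble: `cluster`,
#'   `representative` id, `sequence`, `abundance`, `n_members`, `species`,
#'   `origin` of the representative).
#' @export
greedy_cluster <- function(haplotypes, threshold = 0.99) {
  if (threshold <= 0 || threshold > 1) stop_param("threshold must be in (0, 1]")
  if (is.character(haplotypes)) {
    haplotypes <- tibble(haplotype = sprintf("h%04d", seq_along(haplotypes)),
                         sequence = haplotypes, count = 1L,
                         species = NA_character_, origin = NA_character_)
  }
  empty <- structure(list(
    members = tibble(haplotype = character(), cluster = character()),
    clusters = tibble(cluster = character(), representative = character(),
                      sequence = character(), abundance = integer(),
                      n_members = integer(), species = character(),
                      origin = character())
  ), class = "sat_clusters")
  if (nrow(haplotypes) == 0L) return(empty)

  h <- dplyr::arrange(haplotypes, dplyr::desc(.data$count),
                      dplyr::desc(nchar(.data$sequence)), .data$sequence)
  rep_seq <- character(0)
  rep_idx <- integer(0)
  assign <- integer(nrow(h))
  for (i in seq_len(nrow(h))) {
    hit <- 0L
    if (length(rep_seq)) {
      if (any(rep_seq == h$sequence[i])) {
        hit <- which(rep_seq == h$sequence[i])[1]
      } else if (threshold < 1) {
        idy <- align_many(rep_seq, h$sequence[i], type = "global")$identity
        ok <- which(idy >= threshold)
        if (length(ok)) hit <- ok[1]
      } else {
        # threshold 1 with gaps or mismatches can never reach identity 1
        hit <- 0L
      }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, h$sequence[i])
      rep_idx <- c(rep_idx, i)
      hit <- length(rep_seq)
    }
    assign[i] <- hit
  }
  cl_id <- sprintf("c%03d", seq_along(rep_idx))
  members <- tibble(haplotype = h$haplotype, cluster = cl_id[assign])
  clusters <- tibble(
    cluster = cl_id,
    representative = h$haplotype[rep_idx],
    sequence = rep_seq,
    abundance = vapply(seq_along(rep_idx),
                       function(k) sum(h$count[assign == k]), numeric(1)),
    n_members = vapply(seq_along(rep_idx),
                       function(k) sum(assign == k), integer(1)),
    species = h$species[rep_idx],
    origin = h$origin[rep_idx]
  )
  structure(list(members = members, clusters = clusters,
                 threshold = threshold),
            class = "sat_clusters")
}

#' Pairwise-difference distance matrix from an alignment
#'
#' `d_ij` counts mismatching columns where both rows have a base, plus one
#' for each maximal gap run present in exactly one row (an indel of any
#' length is a single mutational event).
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @return Symmetric integer matrix with zero diagonal, labelled by the
#'   alignment names.
#' @export
pairwise_differences <- function(alignment) {
  if (length(unique(nchar(alignment))) != 1L) {
    stop_param("alignment rows must all have the same length")
  }
  k <- length(alignment)
  labs <- names(alignment) %||% sprintf("s%03d", seq_len(k))
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  d <- matrix(0L, k, k, dimnames = list(labs, labs))
  if (k < 2) return(d)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pd <- pair_diff(mat[i, ], mat[j, ], count_gap_events = TRUE)
      d[i, j] <- d[j, i] <- as.integer(pd$diff)
    }
  }
  d
}

#' Minimum spanning tree of haplotypes with mutational-step nodes
#'
#' Kruskal's algorithm over the pairwise-difference matrix with fully
#' deterministic tie-breaking (edge weight, then the lexicographic node-id
#' pair), so the tree is reproducible even when the MST is not unique. Each
#' edge of weight `k` is expanded with `k - 1` intermediate step nodes, so
#' every drawn edge is a single mutational step.
#'
#' @param dm Symmetric distance matrix (see [pairwise_differences()]).
#' @param nodes Optional tibble annotating haplotype nodes: columns `id`
#'   (matching `rownames(dm)`), and optionally `species`, `origin`,
#'   `abundance` (node weight, e.g. summed cluster abundance).
#' @return A list of class `sat_mst`: `graph` (igraph with step nodes
#'   expanded), `edges` (tibble `from`, `to`, `weight` pre-expansion),
#'   `nodes` (haplotype node table incl. step-node count).
#' @export
build_mst <- function(dm, nodes = NULL) {
  ids <- rownames(dm)
  if (is.null(ids)) stop_param("distance matrix must have row names")
  n <- nrow(dm)
  if (is.null(nodes)) nodes <- tibble(id = ids)
  if (!all(c("species", "origin", "abundance") %in% names(nodes))) {
    nodes <- dplyr::mutate(
      nodes,
      species = if ("species" %in% names(nodes)) .data$species else NA_character_,
      origin = if ("origin" %in% names(nodes)) .data$origin else NA_character_,
      abundance = if ("abundance" %in% names(nodes)) .data$abundance else 1
    )
  }
  nodes <- nodes[match(ids, nodes$id), , drop = FALSE]

  edges <- tibble(from = character(), to = character(), weight = integer())
  if (n > 1) {
    pairs <- which(upper.tri(dm), arr.ind = TRUE)
    cand <- tibble(
      from = ids[pairs[, 1]], to = ids[pairs[, 2]],
      weight = as.integer(dm[pairs])
    )
    swap <- cand$from > cand$to
    tmp <- cand$from[swap]; cand$from[swap] <- cand$to[swap]; cand$to[swap] <- tmp
    cand <- dplyr::arrange(cand, .data$weight, .data$from, .data$to)
    parent <- seq_len(n); names(parent) <- ids
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    kept <- logical(nrow(cand))
    for (e in seq_len(nrow(cand))) {
      ra <- find(match(cand$from[e], ids)); rb <- find(match(cand$to[e], ids))
      if (ra != rb) { parent[ra] <- rb; kept[e] <- TRUE }
    }
    edges <- cand[kept, , drop = FALSE]
  }

  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids,
                            species = as.character(nodes$species),
                            origin = as.character(nodes$origin),
                            abundance = as.numeric(nodes$abundance),
                            step = 0)
  n_steps <- 0L
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      w <- max(1L, edges$weight[e])
      chain <- edges$from[e]
      if (w > 1L) {
        stepn <- sprintf("step_%s_%s_%d", edges$from[e], edges$to[e],
                         seq_len(w - 1L))
        g <- igraph::add_vertices(g, w - 1L, name = stepn,
                                  species = NA_character_,
                                  origin = "step", abundance = 0, step = 1)
        chain <- c(chain, stepn)
        n_steps <- n_steps + w - 1L
      }
      chain <- c(chain, edges$to[e])
      for (k in seq_len(length(chain) - 1L)) {
        g <- igraph::add_edges(g, c(chain[k], chain[k + 1L]))
      }
    }
  }
  structure(list(graph = g, edges = edges, nodes = nodes,
                 n_steps = n_steps),
            class = "sat_mst")
}

#' Total weight of a minimum spanning tree
#' @param mst A `sat_mst`.
#' @return Sum of pre-expansion edge weights.
#' @export
mst_weight <- function(mst) sum(mst$edges$weight)

#' Export an MST as GML plus a node table
#'
#' Writes the step-expanded graph in GML (node attributes: `name`, `species`,
#' `origin`, `abundance`, `step`) and a TSV node table; the GML round-trips
#' through [read_mst_gml()].
#'
#' @param mst A `sat_mst`.
#' @param gml_path Output GML path.
#' @param nodes_path Optional output TSV path for the node table.
#' @return Invisibly, `gml_path`.
#' @export
export_graph <- function(mst, gml_path, nodes_path = NULL) {
  tryCatch(
    igraph::write_graph(mst$graph, gml_path, format = "gml"),
    error = function(e) {
      stop_data(sprintf("failed to write GML to '%s': %s", gml_path,
                        conditionMessage(e)))
    }
  )
  if (!is.null(nodes_path)) {
    readr::write_tsv(node_table(mst), nodes_path)
  }
  invisible(gml_path)
}

#' Node table of an MST (haplotype and step nodes)
#' @param mst A `sat_mst`.
#' @return Tibble with `id`, `species`, `origin`, `abundance`, `step`.
#' @export
node_table <- function(mst) {
  g <- mst$graph
  tibble(
    id = igraph::V(g)$name,
    species = igraph::V(g)$species,
    origin = igraph::V(g)$origin,
    abundance = igraph::V(g)$abundance,
    step = as.integer(igraph::V(g)$step)
  )
}

#' Read back a GML graph written by [export_graph()]
#'
#' @param path GML file path.
#' @return An igraph graph.
#' @export
read_mst_gml <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  igraph::V(g)$step <- as.integer(igraph::V(g)$step)
  g
}

#' Species coherence of MST edges
#'
#' Fraction of haplotype-to-haplotype MST edges joining two nodes of the same
#' species, compared with its null distribution under random permutation of
#' species labels. Under concerted evolution (strong within-species
#' homogenization) same-species haplotypes group together, so the observed
#' fraction exceeds the permutation expectation.
#'
#' @param mst A `sat_mst` whose nodes carry `species`.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return Tibble with `observed`, `null_mean`, `p_value` (one-sided,
#'   permutation `(r + 1)/(n + 1)`).
#' @export
mst_species_coherence <- function(mst, n_perm = 999, seed = 1L) {
  edges <- mst$edges
  sp <- setNames(mst$nodes$species, mst$nodes$id)
  if (nrow(edges) == 0L) stop_param("MST has no edges")
  frac_same <- function(labels) {
    mean(labels[edges$from] == labels[edges$to], na.rm = TRUE)
  }
  obs <- frac_same(sp)
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      frac_same(setNames(sample(sp), names(sp)))
    }, numeric(1))
  })
  tibble(
    observed = obs,
    null_mean = mean(perms),
    p_value = (sum(perms >= obs) + 1) / (n_perm + 1)
  )
}
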