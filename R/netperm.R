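# Seed-interactome construction, connectivity counting to a mendelian
# gene set at up to two hops, and an empirical permutation test against
# control seed sets drawn from a null pool.

#' Scored undirected protein-interaction graph
#'
#' Self-loops are dropped; duplicate unordered pairs are collapsed to
#' one edge keeping the maximum confidence score.
#'
#' @param edges data frame with columns `protein_a`, `protein_b`,
#'   `score` (in `[0, 1]`; a missing column defaults to 1).
#' @param nodes optional full node set (isolated proteins included).
#' @return object of class `interactome_graph` with `nodes`, `edges`,
#'   and the underlying [igraph::graph_from_data_frame()] graph.
#' @export
interactome_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (is.null(edges$score)) edges$score <- 1
  stopifnot(all(c("protein_a", "protein_b") %in% names(edges)))
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("interactome_graph: scores must lie in [0, 1]")
  }
  edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  if (nrow(edges)) {
    a <- pmin(edges$protein_a, edges$protein_b)
    b <- pmax(edges$protein_a, edges$protein_b)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -edges$score)
    first <- !duplicated(key[ord])
    edges <- data.frame(protein_a = a[ord][first], protein_b = b[ord][first],
                        score = edges$score[ord][first],
                        stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(nodes, edges$protein_a, edges$protein_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b", "score")],
    directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, igraph = g),
            class = "interactome_graph")
}

#' Read an edge-list TSV as an interactome graph
#'
#' Expects columns protein_a, protein_b, score (tab-delimited, header;
#' `#` comment lines ignored).
#'
#' @param path file path.
#' @return an [interactome_graph()].
#' @export
read_interactome <- function(path) {
  interactome_graph(read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE))
}

#' Read a one-column gene list
#'
#' @param path file path (one id per line, `#` comments ignored).
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

# Dense logical adjacency over graph$nodes after score filtering.
adjacency_logical <- function(graph, score_min = 0) {
  n <- length(graph$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges[graph$edges$score >= score_min, , drop = FALSE]
  if (nrow(e)) {
    ia <- match(e$protein_a, graph$nodes)
    ib <- match(e$protein_b, graph$nodes)
    A[cbind(ia, ib)] <- TRUE
    A[cbind(ib, ia)] <- TRUE
  }
  A
}

#' Build a seed network and its mendelian connectivity
#'
#' Starting from the seed proteins, the first-degree set is their direct
#' interactors (edges below `score_min` removed). A mendelian protein
#' counts as connected when it is adjacent to a seed (first degree) or,
#' with `max_hops = 2`, adjacent to any first-degree node (second degree
#' via an internode). Internodes are the non-seed, non-mendelian
#' first-degree nodes adjacent to at least one connected mendelian
#' protein.
#'
#' @param graph an [interactome_graph()].
#' @param seeds nonempty seed protein set, disjoint from `mendelian`.
#' @param mendelian mendelian protein set.
#' @param score_min minimum edge confidence retained, default 0.
#' @param max_hops connection depth, 1 or 2 (default 2).
#' @return object of class `seed_network`: `seeds`, `first_degree`,
#'   `internodes`, `connected_mendelian`.
#' @export
build_seed_network <- function(graph, seeds, mendelian, score_min = 0,
                               max_hops = 2L) {
  stopifnot(length(seeds) >= 1L, max_hops %in% c(1L, 2L))
  overlap <- intersect(seeds, mendelian)
  if (length(overlap)) {
    stop("build_seed_network: seeds overlap mendelian set: ",
         paste(overlap, collapse = ", "))
  }
  absent <- setdiff(seeds, graph$nodes)
  if (length(absent)) {
    warning("build_seed_network: seed(s) absent from graph (zero degree): ",
            paste(absent, collapse = ", "))
  }
  A <- adjacency_logical(graph, score_min)
  si <- match(intersect(seeds, graph$nodes), graph$nodes)
  first <- if (length(si)) {
    graph$nodes[rowSums(A[, si, drop = FALSE]) > 0]
  } else character(0)
  first <- setdiff(first, seeds)

  mend_in <- intersect(mendelian, graph$nodes)
  mi <- match(mend_in, graph$nodes)
  reach <- unique(c(intersect(seeds, graph$nodes),
                    if (max_hops >= 2L) first))
  ri <- match(reach, graph$nodes)
  connected <- if (length(mi) && length(ri)) {
    mend_in[rowSums(A[mi, ri, drop = FALSE]) > 0]
  } else character(0)

  inter <- character(0)
  if (max_hops >= 2L && length(connected)) {
    ci <- match(connected, graph$nodes)
    cand <- setdiff(setdiff(first, mendelian), seeds)
    if (length(cand)) {
      fi <- match(cand, graph$nodes)
      inter <- cand[rowSums(A[fi, ci, drop = FALSE]) > 0]
    }
  }
  structure(list(seeds = sort(unique(seeds)), first_degree = sort(first),
                 internodes = sort(inter),
                 connected_mendelian = sort(connected)),
            class = "seed_network")
}

#' Count mendelian proteins connected to a seed network
#'
#' Set-valued count: each mendelian protein is counted once regardless
#' of how many paths reach it.
#'
#' @param net a `seed_network` from [build_seed_network()].
#' @return integer count.
#' @export
count_mendelian_connections <- function(net) {
  length(net$connected_mendelian)
}

#' Permutation test of seed-network connectivity to a mendelian set
#'
#' Draws `B` control seed sets of size `length(observed_seeds)` uniformly
#' without replacement from `null_pool` (independently across sets),
#' scores each by its count of connected mendelian proteins, and reports
#' the add-one empirical p-value
#' `p = (1 + #\{null counts >= observed\}) / (B + 1)`, which can never
#' be zero.
#'
#' @param graph an [interactome_graph()].
#' @param observed_seeds the observed seed protein set.
#' @param mendelian mendelian protein set.
#' @param null_pool pool of control genes, disjoint from
#'   `observed_seeds`, at least as large as it.
#' @param B number of control networks, default 1000.
#' @param rng_seed integer seed.
#' @param score_min minimum edge confidence, default 0.
#' @param max_hops connection depth (1 or 2), default 2.
#' @return object of class `permutation_result`: `observed_count`,
#'   `null_counts` (length `B`), `p_emp`, `B`, `rng_seed`.
#' @export
permutation_test <- function(graph, observed_seeds, mendelian, null_pool,
                             B = 1000L, rng_seed = 1L, score_min = 0,
                             max_hops = 2L) {
  if (length(null_pool) < length(observed_seeds)) {
    stop("permutation_test: null pool smaller than the observed seed set")
  }
  if (length(intersect(null_pool, observed_seeds))) {
    stop("permutation_test: null pool overlaps the observed seed set")
  }
  obs_net <- build_seed_network(graph, observed_seeds, mendelian,
                                score_min, max_hops)
  observed <- count_mendelian_connections(obs_net)

  A <- adjacency_logical(graph, score_min)
  storage.mode(A) <- "double"
  n <- length(graph$nodes)
  pool_idx <- match(null_pool, graph$nodes)  # NA = absent, zero degree
  mend_idx <- match(intersect(mendelian, graph$nodes), graph$nodes)
  k <- length(observed_seeds)

  null_counts <- with_seed(rng_seed, {
    S <- matrix(0, n, B)
    for (b in seq_len(B)) {
      pick <- pool_idx[sample.int(length(pool_idx), k)]
      pick <- pick[!is.na(pick)]
      if (length(pick)) S[pick, b] <- 1
    }
    if (max_hops >= 2L) {
      reach <- (S + (A %*% S > 0)) > 0
    } else {
      reach <- S > 0
    }
    storage.mode(reach) <- "double"
    if (length(mend_idx)) {
      hits <- A[mend_idx, , drop = FALSE] %*% reach > 0
      as.integer(colSums(hits))
    } else {
      integer(B)
    }
  })

  p_emp <- (1 + sum(null_counts >= observed)) / (B + 1)
  structure(list(observed_count = observed, null_counts = null_counts,
                 p_emp = p_emp, B = as.integer(B),
                 rng_seed = as.integer(rng_seed),
                 observed_network = obs_net),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "seed-network connectivity: observed %d connected mendelian protein(s)\n",
    x$observed_count))
  cat(sprintf("  %d control networks; null counts %d-%d (median %g)\n",
              x$B, min(x$null_counts), max(x$null_counts),
              stats::median(x$null_counts)))
  cat(sprintf("  empirical p = %.6g\n", x$p_emp))
  invisible(x)
}

#' Write a permutation result as JSON
#'
#' @param x a `permutation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_permutation_json <- function(x, path) {
  jsonlite::write_json(
    list(observed_count = x$observed_count,
         null_counts = as.integer(x$null_counts),
         p_emp = x$p_emp, B = x$B, rng_seed = x$rng_seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
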