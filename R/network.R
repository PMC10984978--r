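# Modified-cosine spectral similarity, molecular-network construction,
# spectral families and spectral-library annotation.

#' Construct a fragment (MS2) spectrum
#'
#' @param precursor_mz Precursor m/z (> 0).
#' @param charge Precursor charge (default 1).
#' @param mz,intensity Fragment peak arrays; peaks with non-positive
#'   intensity are dropped and the rest sorted by m/z.
#' @param feature_id Optional id of the feature this spectrum belongs to.
#' @param rt Optional acquisition RT (minutes).
#' @return An object of class `fragment_spectrum`.
#' @export
fragment_spectrum <- function(precursor_mz, charge = 1L, mz, intensity,
                              feature_id = NA_integer_, rt = NA_real_) {
  stopifnot(precursor_mz > 0, length(mz) == length(intensity))
  keep <- intensity > 0
  ord <- order(mz[keep])
  structure(list(precursor_mz = precursor_mz, charge = as.integer(charge),
                 peaks = cbind(mz = mz[keep][ord], intensity = intensity[keep][ord]),
                 feature_id = feature_id, rt = rt),
            class = "fragment_spectrum")
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat("<fragment spectrum> precursor ", round(x$precursor_mz, 4), " (",
      x$charge, "+), ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

# Candidate fragment pairs for the modified cosine: direct matches
# (|mz_a - mz_b| <= tol) or matches shifted by the precursor difference
# (|mz_a - mz_b - dprec| <= tol). Weights are products of square-root
# intensities. When |dprec| <= zero_shift_tol the shifted channel collapses
# onto the direct one.
cosine_candidates <- function(a, b, fragment_tol, zero_shift_tol = 0) {
  dprec <- a$precursor_mz - b$precursor_mz
  if (abs(dprec) <= zero_shift_tol) dprec <- 0
  ma <- a$peaks[, 1]; mb <- b$peaks[, 1]
  wa <- sqrt(a$peaks[, 2]); wb <- sqrt(b$peaks[, 2])
  out <- NULL
  for (i in seq_along(ma)) {
    d <- ma[i] - mb
    hit <- which(abs(d) <= fragment_tol | abs(d - dprec) <= fragment_tol)
    if (length(hit))
      out <- rbind(out, cbind(i = i, j = hit, w = wa[i] * wb[hit]))
  }
  out
}

# Exact maximum-weight one-to-one matching over candidate pairs.
# The candidate conflict graph is decomposed into connected components and
# each component solved by depth-first branch-and-bound; components larger
# than `max_exact` candidate pairs (pathological) fall back to greedy.
max_weight_matching <- function(cand, max_exact = 25L) {
  if (is.null(cand) || nrow(cand) == 0L) return(list(score = 0, matched = 0L))
  # components over shared i or j
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (cand[a, "i"] == cand[b, "i"] || cand[a, "j"] == cand[b, "j"]) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  score <- 0; matched <- 0L
  for (r in unique(roots)) {
    rows <- cand[roots == r, , drop = FALSE]
    if (nrow(rows) == 1L) {
      score <- score + rows[1, "w"]; matched <- matched + 1L
      next
    }
    rows <- rows[order(-rows[, "w"]), , drop = FALSE]
    if (nrow(rows) > max_exact) {
      res <- greedy_matching(rows)
    } else {
      res <- exact_matching(rows)
    }
    score <- score + res$score; matched <- matched + res$matched
  }
  list(score = score, matched = matched)
}

greedy_matching <- function(rows) {
  ui <- uj <- integer(0); s <- 0; m <- 0L
  for (k in seq_len(nrow(rows))) {
    if (rows[k, "i"] %in% ui || rows[k, "j"] %in% uj) next
    ui <- c(ui, rows[k, "i"]); uj <- c(uj, rows[k, "j"])
    s <- s + rows[k, "w"]; m <- m + 1L
  }
  list(score = s, matched = m)
}

# Branch-and-bound over candidate rows sorted by descending weight.
exact_matching <- function(rows) {
  n <- nrow(rows)
  suffix <- rev(cumsum(rev(rows[, "w"])))
  best_score <- 0; best_m <- 0L
  rec <- function(k, ui, uj, acc, m) {
    if (acc > best_score || (acc == best_score && m > best_m)) {
      best_score <<- acc; best_m <<- m
    }
    if (k > n) return()
    if (acc + suffix[k] <= best_score) return()
    if (!(rows[k, "i"] %in% ui) && !(rows[k, "j"] %in% uj))
      rec(k + 1L, c(ui, rows[k, "i"]), c(uj, rows[k, "j"]),
          acc + rows[k, "w"], m + 1L)
    rec(k + 1L, ui, uj, acc, m)
  }
  rec(1L, integer(0), integer(0), 0, 0L)
  list(score = best_score, matched = best_m)
}

#' Modified cosine similarity of two fragment spectra
#'
#' Fragment peaks match directly (within `fragment_tol`) or shifted by the
#' precursor mass difference, so structural analogs whose fragments carry the
#' mass offset still align. Intensities are square-root weighted; the score
#' is the maximum-weight one-to-one assignment of candidate matches divided
#' by the product of the spectra's vector norms, clipped to [0, 1]. The
#' assignment is solved exactly (branch-and-bound per conflict component),
#' so the score is symmetric and order-independent.
#'
#' @param a,b `fragment_spectrum` objects.
#' @param fragment_tol Fragment ion tolerance in Da (default 0.9).
#' @param zero_shift_tol Precursor differences at or below this are treated
#'   as zero shift (default 0; the network builder passes its precursor
#'   tolerance).
#' @return List with `cosine` and `matched_peaks`.
#' @examples
#' s <- fragment_spectrum(500, 1, mz = c(100, 200, 300), intensity = c(1, 2, 3))
#' modified_cosine(s, s)
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.9, zero_shift_tol = 0) {
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L)
    return(list(cosine = 0, matched_peaks = 0L))
  cand <- cosine_candidates(a, b, fragment_tol, zero_shift_tol)
  mm <- max_weight_matching(cand)
  norm_a <- sqrt(sum(a$peaks[, 2]))
  norm_b <- sqrt(sum(b$peaks[, 2]))
  list(cosine = unname(min(1, max(0, mm$score / (norm_a * norm_b)))),
       matched_peaks = unname(mm$matched))
}

#' Build a molecular network from fragment spectra
#'
#' All spectrum pairs are scored with the modified cosine; an edge is kept
#' iff its cosine exceeds `cosine_threshold` and it has at least
#' `min_matched` matched peaks (default 4, honoring "more than three").
#' Optional GNPS-style topK pruning keeps an edge only if each endpoint
#' ranks the other within its K best neighbors (off by default).
#'
#' @param spectra List of `fragment_spectrum` objects with distinct
#'   `feature_id`s.
#' @param nodes Optional data frame of node attributes with an `id` column
#'   (m/z, RT, abundances...); defaults to ids/precursors from `spectra`.
#' @param cosine_threshold Minimum cosine, exclusive (default 0.7).
#' @param min_matched Minimum matched peaks, inclusive (default 4).
#' @param precursor_tol Precursor m/z tolerance (default 0.02 Da); pairs
#'   closer than this are scored as same-precursor (zero shift).
#' @param fragment_tol Fragment ion tolerance (default 0.9 Da).
#' @param topK Optional integer for mutual top-K edge pruning.
#' @return An object of class `molecular_network`: list with `nodes` (data
#'   frame, including `bioactive` and `annotation` columns) and `edges`
#'   (data frame `node_a`, `node_b` with `node_a < node_b`, `cosine`,
#'   `matched_peaks`, `mass_shift`).
#' @export
build_network <- function(spectra, nodes = NULL, cosine_threshold = 0.7,
                          min_matched = 4L, precursor_tol = 0.02,
                          fragment_tol = 0.9, topK = NULL) {
  ids <- vapply(spectra, function(s) as.integer(s$feature_id), integer(1))
  if (anyDuplicated(ids)) stop("spectra must have distinct feature ids")
  if (is.null(nodes)) {
    nodes <- data.frame(id = ids,
                        mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
                        rt = vapply(spectra, function(s) s$rt, numeric(1)))
  }
  stopifnot("id" %in% names(nodes), all(ids %in% nodes$id))
  if (!"bioactive" %in% names(nodes)) nodes$bioactive <- FALSE
  if (!"annotation" %in% names(nodes)) nodes$annotation <- NA_character_
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  ord <- order(ids)
  spectra <- spectra[ord]; ids <- ids[ord]
  edges <- data.frame(node_a = integer(0), node_b = integer(0),
                      cosine = numeric(0), matched_peaks = integer(0),
                      mass_shift = numeric(0))
  n <- length(spectra)
  if (n > 1L) {
    k <- 0L
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      sc <- modified_cosine(spectra[[i]], spectra[[j]], fragment_tol,
                            zero_shift_tol = precursor_tol)
      if (sc$cosine > cosine_threshold && sc$matched_peaks >= min_matched) {
        k <- k + 1L
        edges[k, ] <- list(min(ids[i], ids[j]), max(ids[i], ids[j]),
                           sc$cosine, sc$matched_peaks,
                           spectra[[j]]$precursor_mz - spectra[[i]]$precursor_mz)
      }
    }
  }
  if (!is.null(topK) && nrow(edges) > 0L) edges <- prune_topk(edges, topK)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "molecular_network")
}

# Mutual top-K pruning: an edge survives iff each endpoint ranks the other
# within its K highest-cosine neighbors.
prune_topk <- function(edges, k) {
  rank_ok <- function(node, other) {
    inc <- edges[edges$node_a == node | edges$node_b == node, , drop = FALSE]
    inc <- inc[order(-inc$cosine), , drop = FALSE]
    nb <- ifelse(inc$node_a == node, inc$node_b, inc$node_a)
    other %in% utils::head(nb, k)
  }
  keep <- vapply(seq_len(nrow(edges)), function(e) {
    rank_ok(edges$node_a[e], edges$node_b[e]) &&
      rank_ok(edges$node_b[e], edges$node_a[e])
  }, logical(1))
  edges[keep, , drop = FALSE]
}

#' @export
print.molecular_network <- function(x, ...) {
  fam <- spectral_families(x)
  cat("<molecular network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges; ", length(fam$families), " spectral families, ",
      fam$singletons, " singletons\n", sep = "")
  invisible(x)
}

#' Spectral families (connected components) of a molecular network
#'
#' @param net A `molecular_network`.
#' @return List with `families` — a list of integer node-id vectors, one per
#'   component with >= 2 nodes, ordered by decreasing size then smallest
#'   member id — and `singletons`, the count of isolated nodes.
#' @export
spectral_families <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  ids <- as.integer(igraph::V(g)$name)
  groups <- split(ids, comp$membership)
  fams <- Filter(function(v) length(v) >= 2L, groups)
  fams <- lapply(fams, sort)
  if (length(fams)) {
    o <- order(-vapply(fams, length, integer(1)),
               vapply(fams, min, integer(1)))
    fams <- unname(fams[o])
  } else fams <- list()
  list(families = fams,
       singletons = sum(vapply(groups, length, integer(1)) == 1L))
}

#' Convert a molecular network to an igraph object
#'
#' Node ids become vertex names; all node and edge attributes are carried
#' over.
#'
#' @param net A `molecular_network`.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "molecular_network"))
  verts <- net$nodes
  verts$name <- as.character(verts$id)
  verts$id <- NULL   # vertex names carry the ids; a literal id attribute
                     # collides with GraphML vertex ids on read-back
  verts <- verts[, c("name", setdiff(names(verts), "name")), drop = FALSE]
  ed <- net$edges
  if (nrow(ed) > 0L) {
    ed$from <- as.character(ed$node_a); ed$to <- as.character(ed$node_b)
    ed <- ed[, c("from", "to", "cosine", "matched_peaks", "mass_shift")]
  } else {
    ed <- data.frame(from = character(0), to = character(0))
  }
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

#' Annotate spectra against a spectral library
#'
#' Scores every query against every library entry with the modified cosine
#' and reports the best hit meeting both thresholds (score above
#' `score_min` and at least `matched_min` matched peaks).
#'
#' @param spectra List of query `fragment_spectrum` objects.
#' @param library Named list of annotated `fragment_spectrum` objects (names
#'   are the compound annotations).
#' @param score_min Minimum score, exclusive (default 0.7).
#' @param matched_min Minimum matched peaks, inclusive (default 3).
#' @param fragment_tol Fragment tolerance (default 0.9 Da).
#' @return Data frame with one row per query: `feature_id`, `annotation`
#'   (NA when nothing passes), `score`, `matched_peaks`.
#' @export
library_search <- function(spectra, library, score_min = 0.7, matched_min = 3L,
                           fragment_tol = 0.9) {
  if (length(library) == 0L) stop("spectral library is empty")
  if (is.null(names(library)) || any(!nzchar(names(library))))
    stop("library entries must be named with their annotations")
  out <- data.frame(feature_id = vapply(spectra, function(s) as.integer(s$feature_id),
                                        integer(1)),
                    annotation = NA_character_, score = NA_real_,
                    matched_peaks = NA_integer_)
  for (q in seq_along(spectra)) {
    best <- NULL
    for (l in seq_along(library)) {
      sc <- modified_cosine(spectra[[q]], library[[l]], fragment_tol)
      if (sc$cosine > score_min && sc$matched_peaks >= matched_min &&
          (is.null(best) || sc$cosine > best$cosine)) {
        best <- c(sc, list(name = names(library)[l]))
      }
    }
    if (!is.null(best)) {
      out$annotation[q] <- best$name
      out$score[q] <- best$cosine
      out$matched_peaks[q] <- best$matched_peaks
    }
  }
  out
}

#' Write a molecular network as GraphML / edge-list TSV
#'
#' GraphML (readable by Cytoscape) carries all node attributes (m/z, RT,
#' abundance, bioactive flag, annotation) and edge attributes (cosine,
#' matched peaks, mass shift).
#'
#' @param net A `molecular_network`.
#' @param path Output path.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  # igraph requires logicals as character/numeric for graphml stability
  if ("bioactive" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$bioactive <- as.integer(igraph::V(g)$bioactive)
  if ("annotation" %in% igraph::vertex_attr_names(g)) {
    ann <- igraph::V(g)$annotation
    igraph::V(g)$annotation <- ifelse(is.na(ann), "", ann)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edgelist_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a GraphML file back into a molecular network
#'
#' Round-trips the output of [write_graphml()] (bioactive flags restored to
#' logical).
#'
#' @param path GraphML file.
#' @return A `molecular_network`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes$id <- as.integer(nodes$name)
  nodes$name <- NULL
  if ("bioactive" %in% names(nodes)) nodes$bioactive <- as.logical(nodes$bioactive)
  if ("annotation" %in% names(nodes))
    nodes$annotation <- ifelse(nzchar(nodes$annotation), nodes$annotation, NA_character_)
  nodes <- nodes[order(nodes$id), c("id", setdiff(names(nodes), "id")), drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(node_a = pmin(as.integer(ed$from), as.integer(ed$to)),
                      node_b = pmax(as.integer(ed$from), as.integer(ed$to)),
                      cosine = if (nrow(ed)) ed$cosine else numeric(0),
                      matched_peaks = if (nrow(ed)) as.integer(ed$matched_peaks) else integer(0),
                      mass_shift = if (nrow(ed)) ed$mass_shift else numeric(0))
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "molecular_network")
}
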