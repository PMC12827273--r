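# Constraint-based causal discovery: PC skeleton search with Fisher-Z
# tests, v-structure orientation, Meek rules, and tiered background
# knowledge (demographics -> imaging -> scores).
#
# Graph representation: adjacency matrix `amat` with amat[i, j] = 1 when an
# edge mark points from i to j. Undirected edge: amat[i, j] = amat[j, i]
# = 1; directed i -> j: amat[i, j] = 1, amat[j, i] = 0.

new_causal_graph <- function(nodes, amat, sepsets = list()) {
  dimnames(amat) <- list(nodes, nodes)
  structure(list(nodes = nodes, amat = amat, sepsets = sepsets),
            class = "causal_graph")
}

sepset_key <- function(x, y) paste(sort(c(x, y)), collapse = "|")

#' Edges of a causal graph
#' @param graph a `causal_graph`.
#' @return data.frame with columns `from`, `to`, `type`
#'   (`"directed"`/`"undirected"`); undirected edges listed once with
#'   `from` < `to`.
#' @export
graph_edges <- function(graph) {
  a <- graph$amat
  out <- list()
  nodes <- graph$nodes
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i == j || a[i, j] == 0) next
    if (a[j, i] == 1) {                     # undirected, emit once
      if (i < j) out[[length(out) + 1L]] <-
          data.frame(from = nodes[i], to = nodes[j], type = "undirected")
    } else {
      out[[length(out) + 1L]] <-
        data.frame(from = nodes[i], to = nodes[j], type = "directed")
    }
  }
  if (!length(out)) {
    return(data.frame(from = character(), to = character(),
                      type = character()))
  }
  do.call(rbind, out)
}

#' @export
print.causal_graph <- function(x, ...) {
  e <- graph_edges(x)
  cat("causal graph:", length(x$nodes), "nodes,", nrow(e), "edges\n")
  if (nrow(e)) {
    sym <- ifelse(e$type == "directed", "->", "--")
    cat(paste0("  ", e$from, " ", sym, " ", e$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a graph as an edge list or DOT file
#' @param graph a `causal_graph`.
#' @param path output file; `format = "dot"` writes Graphviz DOT,
#'   `"edgelist"` a tab-separated from/to/type table.
#' @param format `"edgelist"` (default) or `"dot"`.
#' @export
write_graph <- function(graph, path, format = c("edgelist", "dot")) {
  format <- match.arg(format)
  e <- graph_edges(graph)
  if (format == "edgelist") {
    utils::write.table(e, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    sym <- ifelse(e$type == "directed", " -> ", " -> ")
    attrs <- ifelse(e$type == "directed", ";", " [dir=none];")
    lines <- c("digraph G {",
               paste0('  "', graph$nodes, '";'),
               if (nrow(e)) paste0('  "', e$from, '"', sym, '"', e$to, '"', attrs),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

# Fisher-Z CI test against a precomputed correlation matrix (fast path).
ci_pvalue <- function(R, n, i, j, S) {
  k <- length(S)
  r <- if (k == 0) R[i, j] else partial_cor_from_corr(R[c(i, j, S), c(i, j, S)])
  r <- max(min(r, 1 - 1e-12), -(1 - 1e-12))
  2 * stats::pnorm(-abs(sqrt(n - k - 3) * atanh(r)))
}

#' PC skeleton search
#'
#' Starts from the complete undirected graph over the columns of `data` and
#' removes the edge (x, y) whenever some conditioning set S drawn from the
#' current adjacents of x (|S| <= `max_cond_size`) renders x and y
#' conditionally independent by the Fisher-Z test at level `alpha`. The
#' separating set of every removed edge is recorded. Variables and
#' conditioning sets are scanned in deterministic lexicographic order, so
#' the output is reproducible and invariant to row order.
#'
#' @param data complete-case data.frame of numeric columns.
#' @param alpha significance level (default 0.05).
#' @param max_cond_size maximum conditioning-set size (default 3).
#' @return a `causal_graph` with undirected edges and recorded sepsets.
#' @export
pc_skeleton <- function(data, alpha = 0.05, max_cond_size = 3L) {
  if (anyNA(data)) stopf("pc_skeleton: complete-case data required")
  nodes <- sort(names(data))
  p <- length(nodes)
  M <- as.matrix(data[, nodes, drop = FALSE])
  storage.mode(M) <- "double"
  n <- nrow(M)
  R <- stats::cor(M)
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepsets <- list()
  for (l in 0:max_cond_size) {
    if (n <= l + 3) break
    any_tested <- FALSE
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j || !adj[i, j]) next
      nbrs <- setdiff(which(adj[i, ]), j)
      if (length(nbrs) < l) next
      any_tested <- TRUE
      subsets <- if (l == 0) {
        list(integer())
      } else if (length(nbrs) == 1L) {
        list(nbrs)                          # combn(n, k) would mean 1:n
      } else {
        utils::combn(nbrs, l, simplify = FALSE)
      }
      for (S in subsets) {
        if (ci_pvalue(R, n, i, j, S) > alpha) {
          adj[i, j] <- adj[j, i] <- FALSE
          sepsets[[sepset_key(nodes[i], nodes[j])]] <- nodes[S]
          break
        }
      }
    }
    if (!any_tested) break
  }
  new_causal_graph(nodes, ifelse(adj, 1L, 0L), sepsets)
}

# TRUE if the directed part of amat contains a cycle.
has_directed_cycle <- function(amat) {
  d <- (amat == 1) & (t(amat) == 0)        # strictly directed edges
  p <- nrow(d)
  indeg <- colSums(d)
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- which(d[v, ])
    for (w in out) {
      d[v, w] <- FALSE
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < p && any(indeg > 0)
}

#' Orient skeleton edges
#'
#' Applies tiered background knowledge first (an ordered list of node
#' sets; causation may not point from a later tier to an earlier one:
#' every between-tier edge is oriented earlier -> later), then the
#' v-structure rule (x -> z <- y for every unshielded triple whose
#' separating set excludes z), then Meek rules 1-3 to closure. A
#' v-structure demanding the reversal of a tier-oriented edge is skipped
#' by default — background knowledge takes precedence over finite-sample
#' collider evidence — or raises an orientation-conflict error naming the
#' edge when `strict = TRUE`. The result is checked to be acyclic in its
#' directed part.
#'
#' @param skeleton a `causal_graph` from [pc_skeleton()] (with sepsets).
#' @param tiers optional list of character vectors, earliest tier first.
#' @param strict error on tier/v-structure conflicts instead of skipping.
#' @return a `causal_graph` with directed and undirected edges.
#' @export
orient_edges <- function(skeleton, tiers = NULL, strict = FALSE) {
  nodes <- skeleton$nodes
  a <- skeleton$amat
  p <- length(nodes)
  und <- function(i, j) a[i, j] == 1 && a[j, i] == 1
  dir_ij <- function(i, j) a[i, j] == 1 && a[j, i] == 0

  # tier background knowledge first: orient all between-tier edges
  if (!is.null(tiers)) {
    tier_of <- rep(NA_integer_, p)
    for (t in seq_along(tiers)) {
      tier_of[match(intersect(tiers[[t]], nodes), nodes)] <- t
    }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (is.na(tier_of[i]) || is.na(tier_of[j])) next
      if (tier_of[i] >= tier_of[j]) next
      if (und(i, j)) { a[i, j] <- 1L; a[j, i] <- 0L }
    }
  }

  # v-structures (cannot reverse a background-oriented edge)
  for (z in seq_len(p)) {
    nb <- which(a[z, ] != 0 | a[, z] != 0)
    nb <- setdiff(nb, z)
    if (length(nb) < 2) next
    for (x in nb) for (y in nb) {
      if (x >= y) next
      if (a[x, y] != 0 || a[y, x] != 0) next            # shielded
      ss <- skeleton$sepsets[[sepset_key(nodes[x], nodes[y])]]
      if (is.null(ss) || nodes[z] %in% ss) next
      for (w in c(x, y)) {
        if (und(w, z)) {
          a[w, z] <- 1L; a[z, w] <- 0L
        } else if (dir_ij(z, w) && strict) {
          stopf("orientation-conflict error: v-structure %s -> %s contradicts tier order",
                nodes[w], nodes[z])
        }
      }
    }
  }

  # Meek rules 1-3 to closure
  repeat {
    changed <- FALSE
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j || !und(i, j)) next
      # R1: k -> i, i - j, k and j nonadjacent  =>  i -> j
      for (k in seq_len(p)) {
        if (k == i || k == j) next
        if (dir_ij(k, i) && a[k, j] == 0 && a[j, k] == 0) {
          a[i, j] <- 1L; a[j, i] <- 0L; changed <- TRUE; break
        }
      }
      if (!und(i, j)) next
      # R2: i -> k -> j and i - j  =>  i -> j
      for (k in seq_len(p)) {
        if (k == i || k == j) next
        if (dir_ij(i, k) && dir_ij(k, j)) {
          a[i, j] <- 1L; a[j, i] <- 0L; changed <- TRUE; break
        }
      }
      if (!und(i, j)) next
      # R3: i - k, i - l, k -> j, l -> j, k and l nonadjacent  =>  i -> j
      ks <- which(vapply(seq_len(p), function(k)
        k != i && k != j && und(i, k) && dir_ij(k, j), TRUE))
      done <- FALSE
      if (length(ks) >= 2) {
        for (k in ks) for (l in ks) {
          if (k >= l || a[k, l] != 0 || a[l, k] != 0) next
          a[i, j] <- 1L; a[j, i] <- 0L; changed <- TRUE; done <- TRUE; break
        }
      }
      if (done) next
    }
    if (!changed) break
  }

  if (has_directed_cycle(a)) {
    stopf("internal error: orientation produced a directed cycle")
  }
  new_causal_graph(nodes, a, skeleton$sepsets)
}

#' Verify candidate confounders
#'
#' Runs the PC algorithm (with tier background knowledge demographics ->
#' imaging -> scores by default) over the candidates, the treatment regions
#' and the outcomes, and corroborates with univariate regressions of every
#' treatment/outcome on each candidate. A candidate satisfies the backdoor
#' requirement when it has directed edges into at least one treatment and
#' at least one outcome.
#'
#' @param data a `cohort_table` or data.frame with the named columns.
#' @param candidates candidate confounder columns (default age, gender).
#' @param treatments region columns to include (default: all regions of the
#'   cohort table; a subset keeps PC fast on wide tables).
#' @param outcomes outcome columns (default mmse, faq).
#' @param alpha significance level (default 0.05).
#' @param max_cond_size maximum PC conditioning-set size (default 3).
#' @param tiers use tiered background knowledge (default TRUE).
#' @return object of class `confounder_report`: per-candidate list with
#'   `directed_to_treatments`, `directed_to_outcomes`, `univariate_p`,
#'   `satisfies_backdoor`; the oriented graph in attribute `graph`.
#' @export
verify_confounders <- function(data, candidates = c("age", "gender"),
                               treatments = NULL,
                               outcomes = c("mmse", "faq"),
                               alpha = 0.05, max_cond_size = 3L,
                               tiers = TRUE) {
  if (is.null(treatments)) treatments <- cohort_regions(data)
  vars <- c(candidates, treatments, outcomes)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stopf("unknown variable(s): %s", paste(miss, collapse = ", "))
  report <- structure(list(), class = "confounder_report")
  if (!length(candidates)) {
    attr(report, "graph") <- NULL
    return(report)
  }
  d <- as.data.frame(data)[, vars]
  g <- pc_skeleton(d, alpha = alpha, max_cond_size = max_cond_size)
  g <- orient_edges(g, tiers = if (tiers)
    list(candidates, treatments, outcomes) else NULL)
  e <- graph_edges(g)
  for (cand in candidates) {
    to <- e$to[e$type == "directed" & e$from == cand]
    uni <- vapply(c(treatments, outcomes), function(v) {
      fit <- stats::lm(d[[v]] ~ d[[cand]])
      stats::coef(summary(fit))[2, 4]
    }, 0)
    report[[cand]] <- list(
      directed_to_treatments = intersect(to, treatments),
      directed_to_outcomes = intersect(to, outcomes),
      univariate_p = uni,
      satisfies_backdoor = length(intersect(to, treatments)) >= 1 &&
        length(intersect(to, outcomes)) >= 1)
  }
  attr(report, "graph") <- g
  class(report) <- "confounder_report"
  report
}
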