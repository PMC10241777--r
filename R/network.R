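#' Build the directed connectivity graph
#'
#' One node per site; a directed edge (i, j) wherever P_ij > 0, weighted
#' `w = -ln(P_ij) >= 0` so that shortest paths maximise the product of
#' connectivity probabilities.
#'
#' @param mat A `connectivity_matrix`.
#' @return An [igraph][igraph::igraph-package] directed graph with vertex
#'   attribute `name` (site id), edge attributes `weight` (-ln P) and `p`.
#' @export
build_graph <- function(mat) {
  stopifnot(inherits(mat, "connectivity_matrix"))
  p <- mat$p
  if (any(p < 0)) stop_spec("build_graph: negative probability")
  adj <- (p > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed",
                                           diag = TRUE)
  igraph::V(g)$name <- as.character(mat$site_id)
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$p <- p[el]
  igraph::E(g)$weight <- -log(p[el])
  g
}

#' Multigenerational stepping-stone connectivity (Floyd-Warshall)
#'
#' All-pairs maximum-product path probabilities: Floyd-Warshall shortest
#' paths on edge weights `-ln(P_ij)`, entirely in log space so chains of
#' hundreds of low-probability steps do not underflow; probabilities are
#' re-exponentiated only in the output. `SS_ii = 1` by convention (the
#' zero-length path; retention stays available in the connectivity
#' matrix). Equal-weight path ties are broken deterministically by the
#' relaxation order (updates on `<=`), so reported paths are reproducible.
#'
#' @param mat A `connectivity_matrix`.
#' @return A `stepping_stone` object: `site_id`, `ss` (probability matrix),
#'   `log_ss` (`-dist`, `-Inf` where unreachable), `reachable` (logical
#'   matrix), and an internal successor matrix for [ss_path()].
#' @export
stepping_stone <- function(mat) {
  stopifnot(inherits(mat, "connectivity_matrix"))
  p <- mat$p
  if (any(p < 0)) stop_spec("stepping_stone: negative probability")
  n <- nrow(p)
  D <- -log(p)
  D[p == 0] <- Inf
  nxt <- matrix(rep(seq_len(n), each = n), n, n)
  nxt[!is.finite(D)] <- NA_integer_
  diag(D) <- 0
  diag(nxt) <- seq_len(n)
  off <- !diag(n)
  for (k in seq_len(n)) {
    alt <- outer(D[, k], D[k, ], `+`)
    upd <- off & is.finite(alt) & alt <= D
    upd[, k] <- FALSE
    upd[k, ] <- FALSE
    if (any(upd)) {
      D[upd] <- alt[upd]
      rows <- row(upd)[upd]
      nxt[upd] <- nxt[cbind(rows, k)]
    }
  }
  ss <- exp(-D)
  ss[!is.finite(D)] <- 0
  diag(ss) <- 1
  structure(list(site_id = mat$site_id, ss = ss, log_ss = -D,
                 reachable = is.finite(D), nxt = nxt),
            class = "stepping_stone")
}

#' Recover the maximising path between two sites
#'
#' @param ss A `stepping_stone` object.
#' @param from,to Site ids (as in `ss$site_id`).
#' @return Integer vector of site ids along the path (including endpoints),
#'   or `integer(0)` if `to` is unreachable from `from`.
#' @export
ss_path <- function(ss, from, to) {
  i <- match(from, ss$site_id); j <- match(to, ss$site_id)
  if (is.na(i) || is.na(j)) stop_spec("ss_path: unknown site id")
  if (i == j) return(ss$site_id[i])
  if (!ss$reachable[i, j]) return(ss$site_id[integer(0)])
  path <- i
  while (i != j) {
    i <- ss$nxt[i, j]
    path <- c(path, i)
    if (length(path) > length(ss$site_id) + 1)
      stop("ss_path: successor cycle (internal error)")
  }
  ss$site_id[path]
}

#' @export
print.stepping_stone <- function(x, ...) {
  n <- length(x$site_id)
  cat(sprintf("<stepping_stone> %d sites, %.1f%% of ordered pairs reachable\n",
              n, 100 * mean(x$reachable[!diag(n)])))
  invisible(x)
}

#' Write stepping-stone and graph artefacts
#'
#' @param ss A `stepping_stone` object.
#' @param path Output CSV path (square SS matrix with a `site_id` column).
#' @export
write_ss_csv <- function(ss, path) {
  m <- as.data.frame(ss$ss)
  names(m) <- ss$site_id
  utils::write.csv(cbind(site_id = ss$site_id, m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ss_csv
#' @param g An igraph graph (from [build_graph()]).
#' @param format `"graphml"` or `"edgelist"` (CSV: from, to, p, weight).
#' @export
write_graph_file <- function(g, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    utils::write.csv(data.frame(from = el[, 1], to = el[, 2],
                                p = igraph::E(g)$p,
                                weight = igraph::E(g)$weight),
                     path, row.names = FALSE)
  }
  invisible(path)
}
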