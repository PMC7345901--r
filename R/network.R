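#' Integer network degrees from system equilibrium constants
#'
#' Identifying the network degree of an antibody with its system
#' equilibrium constant, continuous K_sys values are mapped to integer
#' degrees as `max(1, round(k_sys))`: every B cell keeps at least one
#' link, since a node with no interactions would leave the system. The
#' rounding preserves ordering and the power-law tail index.
#'
#' @param ksys Positive K_sys values.
#' @return Integer degree vector.
#' @examples
#' degrees_from_ksys(c(0.2, 1, 5.4))
#' @export
degrees_from_ksys <- function(ksys) {
  if (!is.numeric(ksys) || any(!is.finite(ksys)) || any(ksys <= 0)) {
    stop("`ksys` must be finite and > 0")
  }
  as.integer(pmax(1, round(ksys)))
}

#' Assign network roles from K_sys values
#'
#' When roles are not available from the simulator, they are assigned from
#' affinity alone: nodes at or below the system median (`K_sys <= 1`) are
#' B1/naive, the top decile within each subnetwork are long-lived plasma
#' cells (hubs), and the remainder are memory B cells. Thresholds are
#' ordering conventions, overridable via `llpc_quantile`.
#'
#' @param ksys Positive K_sys values.
#' @param subnetwork Optional subnetwork labels (LLPC decile is taken per
#'   subnetwork when given).
#' @param llpc_quantile Quantile above which a node is an LLPC hub.
#' @return Character vector of roles (`B1`, `MBC`, `LLPC`).
#' @export
assign_roles_from_ksys <- function(ksys, subnetwork = NULL,
                                   llpc_quantile = 0.9) {
  roles <- rep("MBC", length(ksys))
  roles[ksys <= 1] <- "B1"
  groups <- if (is.null(subnetwork)) rep(1L, length(ksys)) else subnetwork
  for (g in unique(groups)) {
    i <- which(groups == g & ksys > 1)
    if (!length(i)) next
    cutoff <- quantile(ksys[i], llpc_quantile, names = FALSE)
    roles[i[ksys[i] >= cutoff]] <- "LLPC"
  }
  roles
}

#' Build the hierarchical antibody interaction network
#'
#' Nodes are antibody clones; directed links are antigen-transfer pathways
#' from lower to higher energy. Within each subnetwork (structural
#' direction) the long-lived plasma cell is the hub, linked from every
#' other member; additional links connect consecutive energy shells, each
#' node linking to the angularly nearest node in the shell above (ties
#' broken by id). No links cross subnetworks; no self links or duplicates.
#'
#' @param nodes Data frame with columns `id`, `subnetwork`, `shell`,
#'   `role`, and optionally `ksys`.
#' @param directions Optional matrix of unit direction vectors (rows
#'   aligned with `nodes`) used for angular nearest-neighbour choice; when
#'   absent ties fall back to id order.
#' @return A directed [igraph::igraph] graph whose vertices carry the node
#'   attributes.
#' @examples
#' nodes <- data.frame(id = 1:4, subnetwork = 1, shell = c(1, 1, 2, 5),
#'                     role = c("B1", "B1", "MBC", "LLPC"))
#' g <- build_hierarchical_network(nodes)
#' igraph::degree(g)
#' @export
build_hierarchical_network <- function(nodes, directions = NULL) {
  req <- c("id", "subnetwork", "shell", "role")
  if (!all(req %in% names(nodes))) {
    stop("`nodes` needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  edges <- NULL
  for (s in unique(nodes$subnetwork)) {
    mem <- which(nodes$subnetwork == s)
    if (length(mem) < 2L) next
    hubs <- mem[nodes$role[mem] == "LLPC"]
    if (length(hubs) == 0L) {
      warning("subnetwork ", s, " has no LLPC; using its max-shell node ",
              "as the hub")
      hubs <- mem[order(-nodes$shell[mem], nodes$id[mem])][1]
    }
    hub <- hubs[order(-nodes$shell[hubs], nodes$id[hubs])][1]
    others <- setdiff(mem, hub)
    edges <- rbind(edges,
                   cbind(nodes$id[others], rep(nodes$id[hub], length(others))))
    # shell-chain links: each node to one node in the next shell up
    shells <- sort(unique(nodes$shell[mem]))
    for (sh in shells[-length(shells)]) {
      lower <- mem[nodes$shell[mem] == sh]
      upper_sh <- min(shells[shells > sh])
      upper <- mem[nodes$shell[mem] == upper_sh]
      for (v in lower) {
        if (!is.null(directions)) {
          cosv <- directions[upper, , drop = FALSE] %*% directions[v, ]
          best <- upper[order(-cosv, nodes$id[upper])][1]
        } else {
          best <- upper[order(nodes$id[upper])][1]
        }
        edges <- rbind(edges, cbind(nodes$id[v], nodes$id[best]))
      }
    }
  }
  vertices <- data.frame(name = as.character(nodes$id),
                         subnetwork = as.character(nodes$subnetwork),
                         shell = nodes$shell, role = nodes$role)
  if (!is.null(nodes$ksys)) vertices$ksys <- nodes$ksys
  if (is.null(edges)) {
    return(igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = TRUE, vertices = vertices))
  }
  ed <- unique(data.frame(from = as.character(edges[, 1]),
                          to = as.character(edges[, 2])))
  ed <- ed[ed$from != ed$to, ]
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = vertices)
}

#' Fit the degree exponent of a network
#'
#' Maximum-likelihood estimate of the exponent `gamma` of a power-law
#' degree distribution `p(k) ~ k^-gamma`, using the continuous Pareto
#' (Hill) estimator with the standard half-integer shift:
#' `gamma = 1 + n / sum(log(k_i / (k_min - 0.5)))` over degrees
#' `k_i >= k_min`. The default `k_min = 5` keeps the small-degree bias of
#' the continuous approximation under a couple of percent.
#'
#' @param x An [igraph::igraph] graph or an integer degree sequence.
#' @param k_min Smallest degree included in the fit.
#' @return A `tail_fit` object (`alpha` is the estimate of gamma).
#' @export
fit_degree_exponent <- function(x, k_min = 5) {
  degrees <- if (inherits(x, "igraph")) {
    igraph::degree(igraph::as_undirected(x, mode = "collapse"))
  } else {
    x
  }
  if (any(degrees < 0)) stop("degrees must be >= 0")
  tail <- degrees[degrees >= k_min]
  n <- length(tail)
  if (n < 10L) {
    stop("insufficient tail: need at least 10 nodes with degree >= ",
         k_min, ", got ", n)
  }
  fit <- fit_tail_exponent(as.numeric(tail), k_min = k_min - 0.5)
  fit$k_min <- k_min
  fit
}

greedy_box_cover_once <- function(dist_mat, lb, order) {
  boxes <- list()
  for (v in order) {
    placed <- FALSE
    for (b in seq_along(boxes)) {
      if (all(dist_mat[v, boxes[[b]]] < lb)) {
        boxes[[b]] <- c(boxes[[b]], v)
        placed <- TRUE
        break
      }
    }
    if (!placed) boxes[[length(boxes) + 1L]] <- v
  }
  length(boxes)
}

#' Greedy box covering and fractal box dimension of a network
#'
#' Tiles the network with the smallest found number of boxes of diameter
#' bounded by `l_B` (all nodes in a box pairwise within distance
#' `< l_B`), using the greedy colouring formulation with `restarts`
#' random node orders (the minimum cover found is kept). The box
#' dimension `d_B` is the negative slope of `log N_B` against `log l_B`,
#' fitted only over the scaling region `1 < N_B < N` (saturated ends are
#' excluded). Disconnected graphs are reduced to their largest component
#' with a warning.
#'
#' @param g An [igraph::igraph] graph.
#' @param lb_values Box sizes `l_B >= 1` to evaluate.
#' @param restarts Number of random restarts per box size.
#' @return An object of class `box_cover`: list with `lb`, `n_boxes`,
#'   `d_b`, `d_b_stderr`, `n_nodes` and `n_fit` (points used in the fit).
#' @examples
#' g <- igraph::make_ring(32, circular = FALSE)
#' box_covering(g, 2:6)$d_b # ~1 for a path
#' @export
box_covering <- function(g, lb_values = 2:8, restarts = 10) {
  stopifnot(inherits(g, "igraph"))
  if (any(lb_values < 1)) stop("`lb_values` must be >= 1")
  if (!igraph::is_connected(igraph::as_undirected(g, mode = "collapse"))) {
    warning("graph is disconnected; using the largest component")
    comp <- igraph::components(g, mode = "weak")
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  }
  dist_mat <- igraph::distances(g, mode = "all")
  n <- nrow(dist_mat)
  n_boxes <- vapply(lb_values, function(lb) {
    if (lb == 1) return(n)
    best <- n
    for (r in seq_len(restarts)) {
      best <- min(best, greedy_box_cover_once(dist_mat, lb, sample.int(n)))
    }
    best
  }, numeric(1))
  keep <- n_boxes > 1 & n_boxes < n
  d_b <- NA_real_
  d_b_stderr <- NA_real_
  if (sum(keep) >= 3L) {
    fit <- lm(log(n_boxes[keep]) ~ log(lb_values[keep]))
    d_b <- -coef(fit)[[2]]
    d_b_stderr <- summary(fit)$coefficients[2, 2]
  }
  structure(
    list(lb = lb_values, n_boxes = setNames(n_boxes, lb_values),
         d_b = d_b, d_b_stderr = d_b_stderr, n_nodes = n,
         n_fit = sum(keep)),
    class = "box_cover"
  )
}

#' @export
print.box_cover <- function(x, ...) {
  cat("box_cover over", x$n_nodes, "nodes\n")
  print(x$n_boxes)
  cat(sprintf("d_B = %.3f (se %.3f, %d points)\n",
              x$d_b, x$d_b_stderr, x$n_fit))
  invisible(x)
}

#' Box dimension predicted from the degree exponent
#'
#' For a scale-free fractal network the box dimension is tied to the
#' degree exponent by `d_B = (gamma - 1) / (gamma - 2)`; the relation
#' diverges as `gamma` approaches 2 from above and is reported as `Inf`
#' for `gamma <= 2`. The golden-ratio exponent `phi + 1` is the unique
#' fixed point of the map (see [ideal_exponent]).
#'
#' @param gamma Degree exponent value(s).
#' @return Predicted box dimension(s).
#' @examples
#' eq10_box_dimension(3) # 2
#' @export
eq10_box_dimension <- function(gamma) {
  if (!is.numeric(gamma) || any(!is.finite(gamma))) {
    stop("`gamma` must be finite")
  }
  ifelse(gamma > 2, (gamma - 1) / (gamma - 2), Inf)
}

#' Ideal degree exponent: the golden-ratio fixed point
#'
#' The unique exponent at which the degree exponent equals the box
#' dimension it predicts, `gamma = (gamma - 1)/(gamma - 2)`, found by
#' bisection on (2, 4) to 1e-12. The fixed point is `phi + 1 = phi^2`
#' with `phi = (1 + sqrt(5))/2` the golden ratio (about 2.6180339887),
#' and the returned value is checked against that closed form.
#'
#' @return The ideal exponent, a single number.
#' @export
ideal_exponent <- function() {
  f <- function(g) g - (g - 1) / (g - 2)
  lo <- 2 + 1e-9
  hi <- 4
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-13) break
  }
  g <- (lo + hi) / 2
  phi <- (1 + sqrt(5)) / 2
  stopifnot(abs(g - (phi + 1)) < 1e-10)
  g
}

#' Grow a preferential-attachment network
#'
#' Standard degree-proportional attachment growth (each new node attaches
#' `m` links to existing nodes with probability proportional to degree),
#' provided to contrast its emergent degree exponent (about 3) with the
#' model's ideal golden-ratio exponent. Wraps [igraph::sample_pa].
#'
#' @param n_nodes Number of nodes, >= 2.
#' @param m_links_per_node Links added per new node, >= 1.
#' @param seed Optional RNG seed.
#' @return An undirected [igraph::igraph] graph.
#' @export
grow_preferential_attachment <- function(n_nodes, m_links_per_node = 2,
                                         seed = NULL) {
  if (n_nodes < m_links_per_node + 1) {
    stop("`n_nodes` must exceed `m_links_per_node`")
  }
  with_seed(seed,
            igraph::sample_pa(n_nodes, m = m_links_per_node,
                              directed = FALSE))
}

#' Write / read an interaction network in GraphML
#'
#' Round-trip safe export of networks with their node attributes
#' (`ksys`, `role`, `shell`, `subnetwork`).
#'
#' @param g An [igraph::igraph] graph.
#' @param path File path.
#' @return `write_interaction_network` returns `path` invisibly;
#'   `read_interaction_network` returns the graph.
#' @export
write_interaction_network <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_interaction_network
#' @export
read_interaction_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
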