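# Independent oracles and graph fixtures used across the suite.

# (u,v)-flower: start from a single edge and repeatedly replace every edge
# by two parallel paths of u and v edges. With u = v = 2 the graph is a
# deterministic fractal with box dimension log(u+v)/log(u) = 2.
flower_graph <- function(u = 2, v = 2, gen = 3) {
  el <- matrix(c(1, 2), ncol = 2)
  n_max <- 2L
  for (g in seq_len(gen)) {
    new_el <- NULL
    for (i in seq_len(nrow(el))) {
      a <- el[i, 1]; b <- el[i, 2]
      for (len in c(u, v)) {
        prev <- a
        if (len > 1) {
          for (j in seq_len(len - 1)) {
            n_max <- n_max + 1L
            new_el <- rbind(new_el, c(prev, n_max))
            prev <- n_max
          }
        }
        new_el <- rbind(new_el, c(prev, b))
      }
    }
    el <- new_el
  }
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Exact minimum box cover for small graphs. A box of size l_B is a set of
# nodes pairwise within distance < l_B, i.e. a clique of the (l_B-1)-th
# graph power; the minimum cover is the clique-cover number, found by
# branch-and-bound graph colouring of the complement.
brute_force_box_cover <- function(g, lb) {
  d <- igraph::distances(g)
  n <- nrow(d)
  conflict <- d >= lb # cannot share a box
  colourable <- function(k) {
    colours <- integer(n)
    assign_next <- function(v) {
      if (v > n) return(TRUE)
      for (c in seq_len(k)) {
        ok <- TRUE
        for (w in seq_len(v - 1)) {
          if (colours[w] == c && conflict[v, w]) { ok <- FALSE; break }
        }
        if (ok) {
          colours[v] <<- c
          if (assign_next(v + 1)) return(TRUE)
          colours[v] <<- 0L
        }
      }
      FALSE
    }
    assign_next(1)
  }
  for (k in 1:n) if (colourable(k)) return(k)
  n
}

# Inverse-CDF sampler for a continuous Pareto tail with pdf ~ x^-alpha
# above x_min.
rpareto <- function(n, alpha, x_min = 1) {
  x_min * runif(n)^(-1 / (alpha - 1))
}

# Discrete power-law sampler p(k) ~ k^-gamma on 1..k_max.
rdiscrete_powerlaw <- function(n, gamma, k_max = 1e6) {
  sample.int(k_max, n, replace = TRUE, prob = (1:k_max)^(-gamma))
}

# Shared small simulation config for structural tests.
small_sim_config <- function(...) {
  sim_config(n_antigens = 20, n_steps = 100, influx_per_step = 15,
             seed = 42, ...)
}
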