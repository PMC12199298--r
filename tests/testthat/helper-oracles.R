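# Independent brute-force oracles and fixture builders shared by the suite.

# Minimum-image distance by exhaustive scan over image translations (wide
# enough to cover points lying several box lengths apart).
brute_min_image <- function(a, b, box_edges) {
  best <- Inf
  for (i in -4:4) for (j in -4:4) for (k in -4:4) {
    d <- b + c(i, j, k) * box_edges - a
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# All simple donor -> release paths with release nodes as terminal sinks,
# by plain recursion over an adjacency list (node names).
brute_wires <- function(nodes, edges) {
  adj <- setNames(vector("list", nrow(nodes)), nodes$name)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- union(adj[[edges$a[i]]], edges$b[i])
    adj[[edges$b[i]]] <- union(adj[[edges$b[i]]], edges$a[i])
  }
  role <- setNames(nodes$role, nodes$name)
  paths <- list()
  recurse <- function(p) {
    last <- p[length(p)]
    if (role[[last]] == "release") {
      paths[[length(paths) + 1L]] <<- p
      return(invisible())
    }
    for (nxt in setdiff(adj[[last]], p))
      if (role[[nxt]] != "donor") recurse(c(p, nxt))
  }
  for (d in nodes$name[nodes$role == "donor"]) recurse(d)
  sort(vapply(paths, paste, character(1), collapse = ">"))
}

# Random wire graph on <= max_nodes nodes with at least one donor and one
# release node.
random_wire_graph <- function(max_nodes = 10) {
  n <- sample(3:max_nodes, 1)
  names_ <- sprintf("n%02d", seq_len(n))
  role <- c("donor", "release",
            sample(c("donor", "relay", "release"), n - 2L, replace = TRUE,
                   prob = c(0.2, 0.6, 0.2)))
  nodes <- data.frame(name = names_, role = role, stringsAsFactors = FALSE)
  pairs <- t(combn(names_, 2))
  keep <- runif(nrow(pairs)) < 0.35
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                      mechanism = "direct", occupancy = NA_real_,
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

# Exhaustive water-bridge oracle: scan every ordered tuple of k distinct
# water oxygens for a chain donor -> w1 -> ... -> wk -> acceptor with all
# links strictly under the cutoff. Coordinates as plain matrices, no box.
brute_bridge <- function(donor, acceptor, waters, k, cutoff) {
  nd <- function(p, q) sqrt(sum((p - q)^2))
  min_to <- function(grp, w) min(apply(grp, 1L, nd, q = w))
  nw <- nrow(waters)
  idx <- seq_len(nw)
  tuples <- as.matrix(do.call(expand.grid, rep(list(idx), k)))
  for (r in seq_len(nrow(tuples))) {
    tt <- tuples[r, ]
    if (anyDuplicated(tt)) next
    ok <- min_to(donor, waters[tt[1], ]) < cutoff &&
      min_to(acceptor, waters[tt[k], ]) < cutoff
    if (ok && k > 1L)
      for (j in seq_len(k - 1L))
        ok <- ok && nd(waters[tt[j], ], waters[tt[j + 1L], ]) < cutoff
    if (ok) return(TRUE)
  }
  FALSE
}

# One-frame toy trajectory: a donor atom, an acceptor atom, and n waters.
toy_bridge_traj <- function(donor_xyz, acceptor_xyz, water_xyz) {
  nw <- nrow(water_xyz)
  atoms <- data.frame(chain = "A", resid = c(1L, 2L, 1000L + seq_len(nw)),
                      resname = c("GLU", "TYR", rep("HOH", nw)),
                      atom = c("OE1", "OH", rep("O", nw)),
                      stringsAsFactors = FALSE)
  coords <- array(0, c(2L, nw + 2L, 3L))
  for (f in 1:2)
    coords[f, , ] <- rbind(donor_xyz, acceptor_xyz, water_xyz)
  trajectory(coords, atoms, dt = 0.1)
}

# Analytic standard error of the occupancy estimate of a two-state
# discrete-time Markov chain (lag-covariance sum in closed form).
telegraph_theta_se <- function(k_on, k_off, dt, n) {
  p <- k_on * dt; q <- k_off * dt
  theta <- p / (p + q)
  r <- 1 - p - q  # lag-1 autocorrelation
  sqrt(theta * (1 - theta) / n * (1 + r) / (1 - r))
}
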