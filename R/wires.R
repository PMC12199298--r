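## Proton-wire contact graph of the Qo site: nodes are protonatable groups
## (quinol oxygens as donors, side chains and the heme propionate as relays,
## solvent-exposed groups as release sites); edges carry the H-bond
## mechanisms connecting them (direct, or bridged by one or two waters).
## Bridges of more than two waters are never admitted.

#' Build a proton-wire contact graph
#'
#' Edges come either from a declared edge list (mechanisms taken at face
#' value) or from contact occupancies, admitted when any mechanism's
#' occupancy reaches `theta_min`. Mechanisms beyond a two-water bridge are
#' rejected with a warning regardless of occupancy.
#'
#' @param nodes data.frame with columns `name`, `role`
#'   (donor / relay / release).
#' @param edges data.frame with columns `a`, `b`, `mechanism` (one of
#'   "direct", "1w", "2w"; one row per mechanism), optional `occupancy`
#'   in [0, 1] and free-text annotation columns.
#' @param theta_min occupancy admission threshold (default 0.05); ignored
#'   for edges whose occupancy is NA (declared edges).
#' @return a `qw_wire_graph`.
#' @export
wire_graph <- function(nodes, edges, theta_min = 0.05) {
  stopifnot(all(c("name", "role") %in% names(nodes)),
            all(c("a", "b", "mechanism") %in% names(edges)))
  if (!all(nodes$role %in% c("donor", "relay", "release")))
    stop("node roles must be donor, relay or release", call. = FALSE)
  if (anyDuplicated(nodes$name)) stop("duplicate node names", call. = FALSE)
  unknown <- setdiff(c(edges$a, edges$b), nodes$name)
  if (length(unknown))
    stop("edge names unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(edges$occupancy)) edges$occupancy <- NA_real_
  bad <- !edges$mechanism %in% c("direct", "1w", "2w")
  if (any(bad)) {
    warning(sum(bad), " edge mechanism(s) with more than two bridging waters ",
            "rejected (two-water rule)")
    edges <- edges[!bad, , drop = FALSE]
  }
  oc <- edges$occupancy
  if (any(!is.na(oc) & (oc < 0 | oc > 1)))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  keep <- is.na(oc) | oc >= theta_min
  edges <- edges[keep, , drop = FALSE]
  ## collapse duplicate rows into one edge with a mechanism set
  key <- apply(cbind(pmin(edges$a, edges$b), pmax(edges$a, edges$b)), 1L,
               paste, collapse = "|")
  edges$pair <- key
  structure(list(nodes = nodes, edges = edges, theta_min = theta_min),
            class = "qw_wire_graph")
}

#' Read a wire graph from node/edge TSV files
#'
#' @param node_path TSV with columns name, role.
#' @param edge_path TSV with columns a, b, mechanism and optionally
#'   occupancy, evidence.
#' @param theta_min admission threshold, as in [wire_graph()].
#' @return a `qw_wire_graph`.
#' @export
read_wire_graph <- function(node_path, edge_path, theta_min = 0.05) {
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                             comment.char = "#")
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                             comment.char = "#")
  wire_graph(nodes, edges, theta_min)
}

#' The curated Qo-site contact graph
#'
#' The package's instance of the wire graph: quinol-head oxygens O1 and O4
#' as proton donors; Y147, E295, Y297, H276 as relays; the Rieske H152, the
#' heme bL propionate-A (PRA) and D278 as release sites. Edges and their
#' mechanisms reflect the contact statistics of the underlying simulation
#' study, shipped as package data.
#'
#' @param theta_min admission threshold.
#' @return a `qw_wire_graph`.
#' @export
qo_site_graph <- function(theta_min = 0.05) {
  read_wire_graph(system.file("extdata", "qo_nodes.tsv", package = "qowire"),
                  system.file("extdata", "qo_edges.tsv", package = "qowire"),
                  theta_min)
}

## adjacency list (names) of an undirected wire graph
adjacency <- function(graph) {
  adj <- stats::setNames(vector("list", nrow(graph$nodes)), graph$nodes$name)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[i]; b <- graph$edges$b[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  lapply(adj, sort)
}

#' Enumerate proton wires
#'
#' All simple paths from each donor to each release node, with release
#' nodes acting as terminal sinks: a path never passes through one release
#' group on the way to another. Wires are distinguished by their node
#' sequence only; multiple mechanisms on an edge do not multiply wires.
#' Output order is deterministic: by donor name, then path length, then
#' lexicographic node sequence.
#'
#' @param graph a `qw_wire_graph` with at least one donor and one release
#'   node.
#' @return list of `qw_wire` objects (fields `path`, `donor`, `release`).
#' @export
enumerate_wires <- function(graph) {
  roles <- stats::setNames(graph$nodes$role, graph$nodes$name)
  donors <- sort(graph$nodes$name[roles[graph$nodes$name] == "donor"])
  releases <- graph$nodes$name[roles[graph$nodes$name] == "release"]
  if (length(donors) == 0L || length(releases) == 0L)
    stop("graph needs at least one donor and one release node", call. = FALSE)
  adj <- adjacency(graph)
  wires <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (roles[[last]] == "release") {
      wires[[length(wires) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in adj[[last]]) {
      if (nxt %in% path) next
      if (roles[[nxt]] == "donor") next  # donors initiate, never relay
      walk(c(path, nxt))
    }
  }
  for (d in donors) walk(d)
  ## deterministic order: donor, then length, then lexicographic sequence
  keys <- vapply(wires, function(p)
    sprintf("%s|%03d|%s", p[1], length(p), paste(p, collapse = ">")),
    character(1))
  wires <- wires[order(keys)]
  lapply(wires, function(p)
    structure(list(path = p, donor = p[1], release = p[length(p)]),
              class = "qw_wire"))
}

#' @export
print.qw_wire <- function(x, ...) {
  cat(paste(x$path, collapse = " -> "), "\n")
  invisible(x)
}

edge_lookup <- function(graph, a, b) {
  key <- paste(min(a, b), max(a, b), sep = "|")
  graph$edges[graph$edges$pair == key, , drop = FALSE]
}

#' Rank wires by bottleneck occupancy
#'
#' Per wire: the node path, the mechanisms and occupancies of each edge,
#' and the minimum edge occupancy along the path (the wire's bottleneck).
#' Wires are ranked by bottleneck descending; wires with any unknown edge
#' occupancy get an unknown bottleneck and rank last.
#'
#' @param wires list of `qw_wire` from [enumerate_wires()].
#' @param graph the `qw_wire_graph` they came from.
#' @return data.frame: wire, donor, release, n_edges, mechanisms,
#'   bottleneck (NA when unknown).
#' @export
wire_report <- function(wires, graph) {
  rows <- lapply(wires, function(w) {
    p <- w$path
    mechs <- character(); bott <- Inf; unknown <- FALSE
    for (i in seq_len(length(p) - 1L)) {
      e <- edge_lookup(graph, p[i], p[i + 1L])
      mechs <- c(mechs, paste(sort(unique(e$mechanism)), collapse = "+"))
      oc <- suppressWarnings(max(e$occupancy, na.rm = TRUE))
      if (!is.finite(oc)) unknown <- TRUE else bott <- min(bott, oc)
    }
    data.frame(wire = paste(p, collapse = ">"), donor = w$donor,
               release = w$release, n_edges = length(p) - 1L,
               mechanisms = paste(mechs, collapse = ";"),
               bottleneck = if (unknown) NA_real_ else bott,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep[order(is.na(rep$bottleneck), -ifelse(is.na(rep$bottleneck), 0,
                                           rep$bottleneck), rep$wire), ,
      drop = FALSE]
}
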