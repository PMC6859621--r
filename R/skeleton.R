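# Morphological thinning and skeleton-graph centerline tracing.

# Zhang-Suen thinning of a logical mask to a 1-px-wide skeleton.
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors clockwise from north: P2..P9
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
        (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
        (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & b >= 2 & b <= 6 & a == 1
      if (pass == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Crossing number (number of 0->1 transitions around the 8-neighborhood)
# and neighbor count for every pixel of a skeleton. Crossing number 1 marks
# endpoints, >= 3 marks branch points; this is robust to the diagonal
# "staircase" triangles that inflate raw graph degree.
skeleton_topology <- function(skel) {
  m <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
  p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
  p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
  p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
  a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
    (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
    (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  list(crossings = a, neighbors = b)
}

# Split a skeleton into ordered branch-free pixel chains.
# Branch pixels (crossing number >= 3) are removed; each remaining connected
# component is ordered by a weighted shortest path between its two farthest
# endpoints (diagonal steps cost sqrt(2)). Spur chains shorter than
# `spur_px` attached to a branch point are discarded, and where exactly two
# surviving chains meet at one branch pixel they are rejoined through it.
skeleton_chains <- function(skel, min_length = 20, spur_px = 5) {
  idx <- which(skel)
  if (length(idx) == 0) return(list())
  nr <- nrow(skel)
  ys <- (idx - 1) %% nr + 1
  xs <- (idx - 1) %/% nr + 1
  topo <- skeleton_topology(skel)
  is_branch <- topo$crossings[idx] >= 3

  id_of <- matrix(0L, nr, ncol(skel))
  id_of[idx] <- seq_along(idx)

  # adjacency among non-branch pixels
  edges <- list(); wts <- list(); k <- 0
  off <- cbind(dy = c(-1, -1, -1, 0), dx = c(-1, 0, 1, 1))  # half-neighborhood
  for (o in seq_len(nrow(off))) {
    y2 <- ys + off[o, 1]; x2 <- xs + off[o, 2]
    ok <- y2 >= 1 & y2 <= nr & x2 >= 1 & x2 <= ncol(skel)
    ok[ok] <- skel[cbind(y2[ok], x2[ok])]
    if (!any(ok)) next
    k <- k + 1
    edges[[k]] <- cbind(seq_along(idx)[ok], id_of[cbind(y2[ok], x2[ok])])
    wts[[k]] <- rep(sqrt(sum(off[o, ]^2)), sum(ok))
  }
  if (k == 0) return(list())
  e <- do.call(rbind, edges)
  w <- unlist(wts)
  keep_e <- !is_branch[e[, 1]] & !is_branch[e[, 2]]
  # Also cut edges that short-circuit a junction: two arm pixels which are
  # both 8-neighbors of the same branch pixel must not stay connected, or
  # deleting the branch pixel would not split the arms.
  if (any(is_branch) && any(keep_e)) {
    for (bp in which(is_branch)) {
      nbr <- which(abs(ys - ys[bp]) <= 1 & abs(xs - xs[bp]) <= 1)
      nbr <- setdiff(nbr, bp)
      if (length(nbr) >= 2) {
        keep_e <- keep_e & !(e[, 1] %in% nbr & e[, 2] %in% nbr)
      }
    }
  }
  if (!any(keep_e)) return(list())
  g <- igraph::graph_from_edgelist(e[keep_e, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep_e]

  comp <- igraph::components(g)
  chains <- list()
  chain_branch <- list()  # branch pixels adjacent to each chain's ends
  full_e <- e  # includes branch adjacency, for rejoin bookkeeping
  ci <- 0
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    members <- members[!is_branch[members]]
    if (length(members) < 2) next
    degs <- igraph::degree(g, v = members)
    ends <- members[degs <= 1]
    if (length(ends) < 2) next  # cycle or degenerate
    sp <- igraph::shortest_paths(g, from = ends[1], to = ends[length(ends)],
                                 weights = igraph::E(g)$weight)$vpath[[1]]
    path <- as.integer(sp)
    if (length(path) < 2) next
    ci <- ci + 1
    chains[[ci]] <- path
    # branch pixels adjacent to either end of this chain
    endpix <- c(path[1], path[length(path)])
    adj <- full_e[full_e[, 1] %in% endpix | full_e[, 2] %in% endpix, ,
                  drop = FALSE]
    nbr <- setdiff(unique(c(adj)), path)
    chain_branch[[ci]] <- nbr[is_branch[nbr]]
  }
  if (ci == 0) return(list())

  lens <- map_dbl(chains, length)
  is_spur <- lens < spur_px & map_int(chain_branch, length) > 0
  chains <- chains[!is_spur]
  chain_branch <- chain_branch[!is_spur]

  # Rejoin chain pairs separated only by a spur's branch cluster: group
  # adjacent branch pixels, and where exactly two surviving chains touch a
  # cluster (a genuine bifurcation touches three) splice them through it.
  bps <- which(is_branch)
  if (length(bps) > 1) {
    sub_e <- e[is_branch[e[, 1]] & is_branch[e[, 2]], , drop = FALSE]
    gb <- igraph::graph_from_edgelist(
      matrix(match(as.vector(sub_e), bps), ncol = 2), directed = FALSE)
    gb <- igraph::add_vertices(gb, max(0, length(bps) - igraph::vcount(gb)))
    bp_cluster <- igraph::components(gb)$membership
  } else {
    bp_cluster <- rep(1L, length(bps))
  }
  for (cl_id in unique(bp_cluster)) {
    members <- bps[bp_cluster == cl_id]
    touching <- which(map_dbl(chain_branch,
                              function(b) length(intersect(b, members))) > 0)
    if (length(touching) != 2) next
    c1 <- chains[[touching[1]]]; c2 <- chains[[touching[2]]]
    near <- function(p) {
      any(abs(ys[members] - ys[p]) <= 1 & abs(xs[members] - xs[p]) <= 1)
    }
    if (near(c1[1])) c1 <- rev(c1)
    if (!near(c2[1])) c2 <- rev(c2)
    # bridge through the cluster pixel closest to both chain ends
    bridge <- members[which.min(
      (ys[members] - ys[c1[length(c1)]])^2 +
        (xs[members] - xs[c1[length(c1)]])^2 +
        (ys[members] - ys[c2[1]])^2 + (xs[members] - xs[c2[1]])^2)]
    chains[[touching[1]]] <- c(c1, bridge, c2)
    chain_branch[[touching[1]]] <- setdiff(
      unique(c(chain_branch[[touching[1]]], chain_branch[[touching[2]]])),
      members)
    chains[[touching[2]]] <- integer(0)
    chain_branch[[touching[2]]] <- integer(0)
  }
  chains <- keep(chains, function(p) length(p) >= 2)

  out <- map(chains, function(p) tibble(x = xs[p], y = ys[p]))
  keep(out, function(ch) {
    sum(sqrt(diff(ch$x)^2 + diff(ch$y)^2)) >= min_length
  })
}

#' Extract vessel centerline chains from a binary mask
#'
#' Thins the mask to a one-pixel skeleton (Zhang-Suen), splits the skeleton
#' graph at branch points, orders each branch-free path, and clips each
#' chain to the analysis annulus (keeping its longest in-annulus run).
#'
#' @param mask Logical vessel mask.
#' @param annulus Optional logical annulus mask of the same dimensions.
#' @param min_length Minimum chain arc length in pixels.
#' @param spur_px Skeleton spurs shorter than this are pruned.
#' @return A list of tibbles with columns `x`, `y` (ordered pixel chains).
#'   Empty (with a warning) if no chain survives.
#' @export
extract_centerlines <- function(mask, annulus = NULL, min_length = 20,
                                spur_px = 5) {
  if (!any(mask)) {
    warn("Empty vessel mask: no centerlines extracted.")
    return(list())
  }
  skel <- thin_mask(mask)
  chains <- skeleton_chains(skel, min_length = 0, spur_px = spur_px)
  if (!is.null(annulus)) {
    chains <- map(chains, function(ch) {
      inside <- annulus[cbind(ch$y, ch$x)]
      if (!any(inside)) return(ch[0, ])
      runs <- rle(inside)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      best <- which(runs$values)[which.max(runs$lengths[runs$values])]
      ch[starts[best]:ends[best], ]
    })
  }
  chains <- keep(chains, function(ch) {
    nrow(ch) >= 2 &&
      sum(sqrt(diff(ch$x)^2 + diff(ch$y)^2)) >= min_length
  })
  if (length(chains) == 0) {
    warn("No centerline chain survived length/annulus filtering.")
  }
  chains
}
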