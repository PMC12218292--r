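#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning: iteratively peels border pixels while preserving
#' topology, leaving a 1-pixel-wide, 8-connected medial representation of
#' each connected component. Thinning retracts line ends by about half the
#' stroke width, so endpoints are restored afterwards by extending along
#' their tangents within the mask (`restore_ends = FALSE` gives the raw
#' thinning result). Empty masks give empty skeletons.
#'
#' @param mask Logical matrix.
#' @param restore_ends Extend endpoints back to the mask ends?
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize_mask <- function(mask, restore_ends = TRUE) {
  if (!is.matrix(mask)) abort("mask must be a matrix")
  m <- mask != 0
  if (!any(m)) return(m)
  orig <- m
  ny <- nrow(m); nx <- ncol(m)
  shift <- function(img, dy, dx) {
    out <- matrix(FALSE, ny, nx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    out[ys, xs] <- img[ys + dy, xs + dx]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # P2..P9 clockwise from north; rows grow downward so north = row - 1
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, ny, nx)
      for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
      if (step == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m <- remove_redundant_pixels(m)
  if (restore_ends && any(m))
    m <- skeleton_matrix(elongate_skeleton(skeleton_graph(m), orig))
  m
}

# Thinning leaves staircase artefacts (double pixels on diagonals) that
# read as spurious junctions. A pixel whose skeleton neighbours are already
# mutually 8-connected without it carries no connectivity and is removed;
# endpoints (one neighbour) are never touched.
remove_redundant_pixels <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  repeat {
    changed <- FALSE
    for (p in which(m)) {
      r <- (p - 1L) %% ny + 1L; c <- (p - 1L) %/% ny + 1L
      rr <- r + neighbor_offsets[, 1]; cc <- c + neighbor_offsets[, 2]
      ok <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx
      rr <- rr[ok]; cc <- cc[ok]
      nb <- which(m[cbind(rr, cc)])
      if (length(nb) < 2) next
      pts <- cbind(rr[nb], cc[nb])
      # single 8-connected component among the neighbours themselves?
      k <- nrow(pts)
      comp <- seq_len(k)
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (max(abs(pts[i, ] - pts[j, ])) <= 1) {
          old <- comp[j]; comp[comp == old] <- comp[i]
        }
      }
      if (length(unique(comp)) == 1) {
        m[p] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

neighbor_offsets <- rbind(
  c(-1, -1), c(-1, 0), c(-1, 1),
  c(0, -1),            c(0, 1),
  c(1, -1),  c(1, 0),  c(1, 1))

# step length between two 8-adjacent pixels (1 axial, sqrt(2) diagonal)
step_lengths <- function(path_rc) {
  if (nrow(path_rc) < 2) return(numeric(0))
  d <- abs(diff(path_rc))
  ifelse(rowSums(d) == 2, sqrt(2), 1)
}

path_length <- function(path_rc) sum(step_lengths(path_rc))

#' Build a skeleton graph from a skeleton image
#'
#' Nodes are endpoints (exactly one skeleton neighbour), junctions (three or
#' more neighbours, adjacent junction pixels merged into one node) and
#' isolated pixels; edges are the branches connecting them, each carrying
#' its ordered pixel path and length (axial steps 1 px, diagonal steps
#' sqrt(2) px). Closed loops without any node get a single anchor pixel and
#' a self-edge.
#'
#' @param skel Logical matrix of skeleton pixels (e.g. from
#'   [skeletonize_mask()]).
#' @return Object of class `skeleton_graph`: `dim`, `pixels` (linear
#'   indices), `nodes` tibble (`node`, `type`, `pixels`), `edges` tibble
#'   (`edge`, `from`, `to`, `path`, `length_px`).
#' @export
skeleton_graph <- function(skel) {
  if (!is.matrix(skel)) abort("skel must be a matrix")
  skel <- skel != 0
  ny <- nrow(skel); nx <- ncol(skel)
  idx <- which(skel)
  empty_nodes <- tibble(node = integer(0), type = character(0),
                        pixels = list())
  empty_edges <- tibble(edge = integer(0), from = integer(0),
                        to = integer(0), path = list(),
                        length_px = numeric(0))
  g <- structure(list(dim = c(ny, nx), pixels = idx,
                      nodes = empty_nodes, edges = empty_edges),
                 class = "skeleton_graph")
  if (!length(idx)) return(g)

  rc <- cbind((idx - 1L) %% ny + 1L, (idx - 1L) %/% ny + 1L)
  inskel <- matrix(FALSE, ny, nx); inskel[idx] <- TRUE
  nb_of <- function(i) {
    r <- (i - 1L) %% ny + 1L; c <- (i - 1L) %/% ny + 1L
    rr <- r + neighbor_offsets[, 1]; cc <- c + neighbor_offsets[, 2]
    ok <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx
    cand <- (cc[ok] - 1L) * ny + rr[ok]
    cand[inskel[cand]]
  }
  nbrs <- lapply(idx, nb_of)
  names(nbrs) <- as.character(idx)
  degree <- setNames(lengths(nbrs), as.character(idx))

  is_node_px <- degree != 2L
  node_px <- idx[is_node_px]
  # merge adjacent junction pixels into single junction nodes
  jmask <- matrix(FALSE, ny, nx)
  jmask[idx[degree >= 3L]] <- TRUE
  jlab <- if (any(jmask)) label_components(jmask) else jmask * 0
  node_id_of <- integer(0)
  nodes <- list()
  nid <- 0L
  if (any(jmask)) {
    for (j in seq_len(max(jlab))) {
      nid <- nid + 1L
      pxs <- which(jlab == j)
      nodes[[nid]] <- list(node = nid, type = "junction", pixels = pxs)
      node_id_of[as.character(pxs)] <- nid
    }
  }
  for (p in idx[degree == 1L]) {
    nid <- nid + 1L
    nodes[[nid]] <- list(node = nid, type = "endpoint", pixels = p)
    node_id_of[as.character(p)] <- nid
  }
  for (p in idx[degree == 0L]) {
    nid <- nid + 1L
    nodes[[nid]] <- list(node = nid, type = "isolated", pixels = p)
    node_id_of[as.character(p)] <- nid
  }

  visited <- setNames(logical(length(idx)), as.character(idx))
  edges <- list()
  eid <- 0L
  add_edge <- function(path_px) {
    eid <<- eid + 1L
    prc <- cbind((path_px - 1L) %% ny + 1L, (path_px - 1L) %/% ny + 1L)
    edges[[eid]] <<- list(
      edge = eid,
      from = node_id_of[[as.character(path_px[1])]],
      to = node_id_of[[as.character(path_px[length(path_px)])]],
      path = path_px, length_px = path_length(prc))
  }
  trace_chain <- function(start, nxt) {
    path <- c(start, nxt)
    prev <- start; cur <- nxt
    while (degree[[as.character(cur)]] == 2L) {
      visited[as.character(cur)] <<- TRUE
      nb <- nbrs[[as.character(cur)]]
      nxt2 <- nb[nb != prev]
      if (length(nxt2) == 0L) break  # closed back on itself
      # prefer an unvisited continuation; fall back to a node pixel
      if (length(nxt2) > 1L) {
        nodey <- nxt2[degree[as.character(nxt2)] != 2L]
        nxt2 <- if (length(nodey)) nodey[1] else nxt2[1]
      }
      if (nxt2 == path[1] && degree[[as.character(nxt2)]] == 2L) {
        path <- c(path, nxt2)  # pure cycle closed
        break
      }
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
    }
    path
  }

  done_pairs <- character(0)
  for (np in node_px) {
    for (nb in nbrs[[as.character(np)]]) {
      dg <- degree[[as.character(nb)]]
      if (dg != 2L) {
        # direct node-node adjacency
        a <- node_id_of[[as.character(np)]]
        b <- node_id_of[[as.character(nb)]]
        if (a == b) next  # intra-junction adjacency
        key <- paste(sort(c(np, nb)), collapse = "-")
        if (key %in% done_pairs) next
        done_pairs <- c(done_pairs, key)
        add_edge(c(np, nb))
      } else {
        if (visited[[as.character(nb)]]) next
        path <- trace_chain(np, nb)
        last <- path[length(path)]
        if (degree[[as.character(last)]] == 2L) next # handled as cycle later
        add_edge(path)
      }
    }
  }
  # pure cycles: remaining unvisited degree-2 pixels with no node in reach
  remaining <- idx[degree == 2L & !visited[as.character(idx)]]
  # drop those that ended up inside recorded paths
  in_paths <- unique(unlist(map(edges, "path")))
  remaining <- setdiff(remaining, in_paths)
  while (length(remaining)) {
    start <- min(remaining)
    nid <- nid + 1L
    nodes[[nid]] <- list(node = nid, type = "cycle", pixels = start)
    node_id_of[as.character(start)] <- nid
    nb <- nbrs[[as.character(start)]]
    path <- trace_chain(start, nb[1])
    if (path[length(path)] != start) path <- c(path, start)
    add_edge(path)
    remaining <- setdiff(remaining, path)
  }

  g$nodes <- bind_rows(map(nodes, function(n)
    tibble(node = n$node, type = n$type, pixels = list(n$pixels))))
  if (eid > 0) {
    g$edges <- bind_rows(map(edges, function(e)
      tibble(edge = e$edge, from = e$from, to = e$to,
             path = list(e$path), length_px = e$length_px)))
  }
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d px, %d nodes, %d edges\n",
              length(x$pixels), nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

skeleton_matrix <- function(g) {
  m <- matrix(FALSE, g$dim[1], g$dim[2])
  m[g$pixels] <- TRUE
  m
}

# edge ids on the weighted diameter path of each component (tree diameter
# via igraph shortest paths; skeletons are trees up to rare cycles)
diameter_edge_ids <- function(g) {
  if (nrow(g$edges) == 0) return(integer(0))
  el <- cbind(g$edges$from, g$edges$to)
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(ig)$weight <- g$edges$length_px
  igraph::E(ig)$eid <- g$edges$edge
  out <- integer(0)
  comps <- igraph::components(ig)
  for (ci in seq_len(comps$no)) {
    vs <- which(comps$membership == ci)
    sub <- igraph::induced_subgraph(ig, vs)
    dp <- igraph::get_diameter(sub, weights = igraph::E(sub)$weight)
    if (length(dp) >= 2) {
      ep <- igraph::E(sub, path = dp)
      out <- c(out, ep$eid)
    }
  }
  out
}

rebuild_from_edges <- function(g, keep_edges) {
  m <- matrix(FALSE, g$dim[1], g$dim[2])
  if (length(keep_edges)) {
    kept <- g$edges$edge %in% keep_edges
    m[unlist(g$edges$path[kept])] <- TRUE
    # interior pixels of a multi-pixel junction node may belong to no edge
    # path; dropping them would split the component
    live_nodes <- unique(c(g$edges$from[kept], g$edges$to[kept]))
    m[unlist(g$nodes$pixels[g$nodes$node %in% live_nodes])] <- TRUE
  }
  # keep isolated node pixels (no incident edges at all)
  iso <- g$nodes$node[g$nodes$type == "isolated"]
  if (length(iso))
    m[unlist(g$nodes$pixels[g$nodes$node %in% iso])] <- TRUE
  # node pixels that only served the removed branch are redundant now
  skeleton_graph(remove_redundant_pixels(m))
}

#' Prune spurious terminal skeleton branches
#'
#' Iteratively removes terminal branches (edges ending at an endpoint whose
#' other end is a junction) that are thinning artefacts: shorter than
#' `min_branch_px` *and* lying entirely within `coverage_radius_px` of the
#' remaining skeleton. The coverage test distinguishes a spur (which covers
#' no mask area of its own, sitting inside the tube width of the branch it
#' sprouts from) from a genuine short arm of a crossed or branched
#' structure, which extends away from the rest of the skeleton. The longest
#' path of a component is never removed and unbranched skeletons are left
#' untouched; the graph is rebuilt after each sweep, so dissolved junctions
#' merge their remaining branches. The operation is idempotent.
#'
#' @param g A [skeleton_graph()].
#' @param min_branch_px Branches shorter than this are candidates for
#'   removal; the default elsewhere in the pipeline is `2 * width_px`.
#' @param coverage_radius_px Spur radius; a candidate is only pruned when
#'   all its pixels lie within this distance of the other branches' paths.
#'   Defaults to half of `min_branch_px` (the tube radius) plus half a
#'   pixel of junction-cluster allowance.
#' @return A pruned `skeleton_graph`.
#' @export
prune_skeleton <- function(g, min_branch_px,
                           coverage_radius_px = (min_branch_px + 1) / 2) {
  stopifnot(inherits(g, "skeleton_graph"), min_branch_px >= 0)
  ny <- g$dim[1]
  to_rc <- function(px) cbind((px - 1L) %% ny + 1L, (px - 1L) %/% ny + 1L)
  repeat {
    if (nrow(g$edges) == 0) return(g)
    deg <- table(factor(c(g$edges$from, g$edges$to),
                        levels = g$nodes$node))
    protected <- diameter_edge_ids(g)
    jn <- g$nodes$node[g$nodes$type == "junction"]
    drop <- integer(0)
    for (i in seq_len(nrow(g$edges))) {
      e <- g$edges[i, ]
      if (e$length_px >= min_branch_px) next
      if (e$edge %in% protected) next
      ends <- c(e$from, e$to)
      is_term <- deg[as.character(ends)] == 1
      # terminal spur: one free end, the other anchored at a junction
      if (!(any(is_term) && any(ends %in% jn))) next
      # coverage is measured against the other branches' paths: junction
      # clusters can absorb the base of a genuine arm, and measuring
      # against the cluster itself would wrongly mark the arm redundant
      rest <- unique(unlist(g$edges$path[g$edges$edge != e$edge]))
      if (!length(rest)) next
      prc <- to_rc(e$path[[1]])
      rrc <- to_rc(rest)
      dmax <- max(vapply(seq_len(nrow(prc)), function(k)
        sqrt(min((rrc[, 1] - prc[k, 1])^2 + (rrc[, 2] - prc[k, 2])^2)),
        numeric(1)))
      if (dmax <= coverage_radius_px) drop <- c(drop, e$edge)
    }
    if (!length(drop)) return(g)
    g <- rebuild_from_edges(g, setdiff(g$edges$edge, drop))
  }
}

#' Elongate skeleton endpoints to fit the mask
#'
#' Extends each endpoint along the local tangent direction (estimated from
#' the last 5 skeleton pixels) one pixel at a time while remaining inside
#' the mask, so the skeleton spans the full structure the mask covers. The
#' output skeleton is always contained in the mask.
#'
#' @param g A [skeleton_graph()] whose pixels lie inside `mask`.
#' @param mask Logical matrix.
#' @param window Tangent-estimation window, pixels.
#' @param max_steps Safety bound on the extension length.
#' @return An elongated `skeleton_graph`.
#' @export
elongate_skeleton <- function(g, mask, window = 5, max_steps = 100) {
  stopifnot(inherits(g, "skeleton_graph"), is.matrix(mask))
  mask <- mask != 0
  if (any(!mask[g$pixels])) abort("skeleton must be contained in mask")
  ny <- g$dim[1]; nx <- g$dim[2]
  m <- skeleton_matrix(g)
  to_rc <- function(px) c((px - 1L) %% ny + 1L, (px - 1L) %/% ny + 1L)

  # Degenerate components first: thinning a small footprint can collapse
  # it to a point or a short remnant lying off (even across) the true
  # axis. A skeleton component that fails to span its mask component
  # (length < 70% of the footprint's principal-axis extent) is
  # re-initialised at the footprint centroid and grown both ways along
  # the footprint's principal axis.
  jobs <- list()
  mlab <- label_components(mask)
  slab <- label_components(m)
  if (max(slab) > 0) {
    # junction-bearing components are branched structures, never remnants
    jpx <- unlist(g$nodes$pixels[g$nodes$type == "junction"])
    has_junction <- unique(slab[jpx])
    reinit_mask_comps <- integer(0)
    for (ci in seq_len(max(slab))) {
      cpx <- which(slab == ci)
      if (ci %in% has_junction || length(cpx) > 6) next
      mask_id <- mlab[cpx[1]]
      mpx <- which(mlab == mask_id)
      if (length(mpx) < 3) next
      rc <- cbind((mpx - 1L) %% ny + 1L, (mpx - 1L) %/% ny + 1L)
      ax <- eigen(stats::cov(rc) + diag(2) / 12,
                  symmetric = TRUE)$vectors[, 1]
      proj <- rc %*% ax
      extent <- diff(range(proj))
      # span of the skeleton component along the footprint's axis: a
      # remnant lying off (or across) the axis projects to almost nothing
      src <- cbind((cpx - 1L) %% ny + 1L, (cpx - 1L) %/% ny + 1L)
      span <- diff(range(src %*% ax))
      if (span < 0.7 * extent && extent >= 2) {
        reinit_mask_comps <- union(reinit_mask_comps, mask_id)
        m[cpx] <- FALSE
      }
    }
    for (mask_id in reinit_mask_comps) {
      mpx <- which(mlab == mask_id)
      if (length(mpx) < 3) next
      rc <- cbind((mpx - 1L) %% ny + 1L, (mpx - 1L) %/% ny + 1L)
      ctr <- colMeans(rc)
      ax <- eigen(stats::cov(rc) + diag(2) / 12,
                  symmetric = TRUE)$vectors[, 1]
      seed <- mpx[which.min((rc[, 1] - ctr[1])^2 + (rc[, 2] - ctr[2])^2)]
      m[seed] <- TRUE
      endc <- to_rc(seed)
      jobs[[length(jobs) + 1]] <- list(endc = endc, d = ax)
      jobs[[length(jobs) + 1]] <- list(endc = endc, d = -ax)
    }
    g <- skeleton_graph(m)
  }

  eps <- g$nodes$node[g$nodes$type == "endpoint"]
  for (nd in eps) {
    px <- g$nodes$pixels[[match(nd, g$nodes$node)]][1]
    ei <- which(g$edges$from == nd | g$edges$to == nd)[1]
    if (is.na(ei)) next
    path <- g$edges$path[[ei]]
    if (path[1] == px) path <- rev(path)
    k <- min(window, length(path) - 1)
    if (k < 1) next
    endc <- to_rc(px)
    backc <- to_rc(path[length(path) - k])
    d <- endc - backc
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) next
    jobs[[length(jobs) + 1]] <- list(endc = endc, d = d / nrm)
  }
  for (job in jobs) {
    cur <- job$endc
    d <- job$d
    for (t in seq_len(max_steps)) {
      # candidate steps: in-mask neighbours within 60 degrees of the
      # running direction; take the best-aligned one (greedy ridge
      # following — a straight-line probe stalls on zigzag tangents)
      best <- NULL; best_proj <- 0.5
      for (k in seq_len(nrow(neighbor_offsets))) {
        p <- cur + neighbor_offsets[k, ]
        if (p[1] < 1 || p[1] > ny || p[2] < 1 || p[2] > nx) next
        if (!mask[p[1], p[2]] || m[p[1], p[2]]) next
        step <- neighbor_offsets[k, ] / sqrt(sum(neighbor_offsets[k, ]^2))
        proj <- sum(step * d)
        if (proj <= best_proj) next
        # never touch skeleton pixels other than the predecessor:
        # elongation must not create junctions or merge components
        nb_r <- pmax(1, p[1] - 1):pmin(ny, p[1] + 1)
        nb_c <- pmax(1, p[2] - 1):pmin(nx, p[2] + 1)
        nbhd <- m[nb_r, nb_c, drop = FALSE]
        nbhd[nb_r == cur[1], nb_c == cur[2]] <- FALSE
        if (any(nbhd)) next
        best <- p; best_proj <- proj
        best_step <- step
      }
      if (is.null(best)) break
      m[best[1], best[2]] <- TRUE
      d <- 0.6 * d + 0.4 * best_step
      d <- d / sqrt(sum(d^2))
      cur <- best
    }
  }
  skeleton_graph(m)
}

#' Complete a skeleton over uncovered mask lobes
#'
#' Thinning can absorb short, wide arms of a branched structure into the
#' main chain, leaving mask lobes with no skeleton coverage. Any connected
#' set of at least `min_lobe_px` mask pixels lying farther than `max_dist`
#' from the skeleton gets a branch: its farthest pixel is joined to the
#' nearest skeleton pixel by a straight digital path (only when that path
#' stays inside the mask). Clean simple tubes, whose every mask pixel sits
#' within the tube half-width of the centreline, are left untouched.
#'
#' @param g A [skeleton_graph()] contained in `mask`.
#' @param mask Logical matrix.
#' @param max_dist Coverage radius in px (default: the 2 px tube width).
#' @param min_lobe_px Minimum uncovered-lobe size to warrant a branch.
#' @return A completed `skeleton_graph`.
#' @export
complete_skeleton <- function(g, mask, max_dist = 2.2, min_lobe_px = 4) {
  stopifnot(inherits(g, "skeleton_graph"), is.matrix(mask))
  mask <- mask != 0
  if (!length(g$pixels)) return(g)
  ny <- g$dim[1]
  m <- skeleton_matrix(g)
  for (iter in 1:4) {
    spx <- which(m)
    src <- cbind((spx - 1L) %% ny + 1L, (spx - 1L) %/% ny + 1L)
    mpx <- which(mask)
    mrc <- cbind((mpx - 1L) %% ny + 1L, (mpx - 1L) %/% ny + 1L)
    dmin <- vapply(seq_along(mpx), function(k)
      sqrt(min((src[, 1] - mrc[k, 1])^2 + (src[, 2] - mrc[k, 2])^2)),
      numeric(1))
    far <- matrix(FALSE, ny, ncol(mask))
    far[mpx[dmin > max_dist]] <- TRUE
    if (!any(far)) break
    flab <- label_components(far)
    sizes <- tabulate(flab[flab > 0])
    big <- which(sizes >= min_lobe_px)
    if (!length(big)) break
    added <- FALSE
    for (id in big) {
      lpx <- which(flab == id)
      ldist <- dmin[match(lpx, mpx)]
      target <- lpx[which.max(ldist)]
      trc <- c((target - 1L) %% ny + 1L, (target - 1L) %/% ny + 1L)
      near <- which.min((src[, 1] - trc[1])^2 + (src[, 2] - trc[2])^2)
      # straight digital path from the nearest skeleton pixel to the lobe
      a <- src[near, ]; b <- trc
      nstep <- max(abs(b - a))
      ok <- TRUE
      path <- matrix(NA_integer_, 0, 2)
      for (t in seq_len(nstep)) {
        p <- round(a + (b - a) * t / nstep)
        if (!mask[p[1], p[2]]) { ok <- FALSE; break }
        path <- rbind(path, p)
      }
      if (ok && nrow(path)) {
        m[path] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  skeleton_graph(m)
}

#' Summarise a skeleton graph (Analyze-Skeleton-style features)
#'
#' @param g A [skeleton_graph()].
#' @return One-row tibble: `n_components`, `n_branches`, `n_junctions`,
#'   `n_endpoints`, `branch_lengths` (list column), `total_length_px`,
#'   `longest_path_px`.
#' @export
skeleton_features <- function(g) {
  stopifnot(inherits(g, "skeleton_graph"))
  if (!length(g$pixels))
    return(tibble(n_components = 0L, n_branches = 0L, n_junctions = 0L,
                  n_endpoints = 0L, branch_lengths = list(numeric(0)),
                  total_length_px = 0, longest_path_px = 0))
  lab <- label_components(skeleton_matrix(g))
  longest <- 0
  if (nrow(g$edges) > 0) {
    el <- cbind(g$edges$from, g$edges$to)
    ig <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::E(ig)$weight <- g$edges$length_px
    comps <- igraph::components(ig)
    for (ci in seq_len(comps$no)) {
      sub <- igraph::induced_subgraph(ig, which(comps$membership == ci))
      dp <- igraph::get_diameter(sub, weights = igraph::E(sub)$weight)
      if (length(dp) >= 2) {
        ep <- igraph::E(sub, path = dp)
        longest <- max(longest, sum(ep$weight))
      }
    }
  }
  tibble(
    n_components = max(lab),
    n_branches = nrow(g$edges),
    n_junctions = sum(g$nodes$type == "junction"),
    n_endpoints = sum(g$nodes$type == "endpoint"),
    branch_lengths = list(g$edges$length_px),
    total_length_px = sum(g$edges$length_px),
    longest_path_px = longest)
}
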