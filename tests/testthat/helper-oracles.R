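# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition, by a different route than the package
# implementation, and are kept slow and simple.

# Exhaustive Otsu: try every split of a histogram, computing class
# weights and means directly from the counts.
oracle_otsu_split <- function(counts) {
  n <- length(counts)
  total <- sum(counts)
  mids <- seq_len(n) - 0.5
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(n - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n] * mids[(k + 1):n]) / n1
    v <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_k <- k }
  }
  best_k
}

# Recursive flood fill over explicit coordinates (stack-based, one voxel
# at a time) counting connected components.
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- switch(as.character(connectivity),
    "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)),
    {
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
      if (connectivity == 18) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
      g
    })
  seen <- array(FALSE, dim = d)
  ncomp <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    stack_ <- start
    seen[start] <- TRUE
    while (length(stack_) > 0L) {
      v <- stack_[length(stack_)]
      stack_ <- stack_[-length(stack_)]
      i0 <- v - 1L
      cy <- i0 %% d[1] + 1L
      cx <- (i0 %/% d[1]) %% d[2] + 1L
      cz <- i0 %/% (d[1] * d[2]) + 1L
      for (r in seq_len(nrow(offs))) {
        y <- cy + offs[r, 1]; x <- cx + offs[r, 2]; z <- cz + offs[r, 3]
        if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) next
        w <- y + (x - 1L) * d[1] + (z - 1L) * d[1] * d[2]
        if (mask[w] && !seen[w]) { seen[w] <- TRUE; stack_ <- c(stack_, w) }
      }
    }
  }
  ncomp
}

# Convex polygon point test: the point must be on the same side of (or
# on) every edge, for counter-clockwise vertex order.
oracle_point_in_convex <- function(px, py, poly) {
  n <- nrow(poly)
  # ensure counter-clockwise order via the shoelace sign
  area2 <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  if (area2 < 0) poly <- poly[n:1, , drop = FALSE]
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
             (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    if (cross < -1e-9) return(FALSE)
  }
  TRUE
}

# Naive per-pixel box filter with replicate padding and the same
# even-kernel centring convention (window offsets -K/2 .. K/2-1).
oracle_box_filter <- function(mat, k) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  offs <- seq_len(k) - (k %/% 2) - 1L
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      s <- 0
      for (dy in offs) for (dx in offs) {
        yy <- min(max(y + dy, 1L), nr)
        xx <- min(max(x + dx, 1L), nc)
        s <- s + mat[yy, xx]
      }
      out[y, x] <- s / (k * k)
    }
  }
  out
}

# Skeleton node/degree oracle via igraph: build the 26-adjacency graph,
# classify vertices by graph degree, and compute the cumulative node
# degree from the components of the graph with all nodes removed (each
# component is one branch interior; it contributes its size plus one for
# each distinct far-end node).
oracle_skeleton_nodes <- function(skel) {
  d <- dim(skel)
  vox <- which(skel)
  nv <- length(vox)
  if (nv == 0L) return(list(node_count = 0L, node_degrees = integer(0)))
  co <- cbind((vox - 1L) %% d[1],
              ((vox - 1L) %/% d[1]) %% d[2],
              (vox - 1L) %/% (d[1] * d[2]))
  edges <- NULL
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      if (j <= i) next
      if (max(abs(co[i, ] - co[j, ])) <= 1L) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  deg <- igraph::degree(g)
  nodes <- which(deg != 2L)
  cum <- integer(length(nodes))
  if (length(nodes) > 0L) {
    interior <- setdiff(seq_len(nv), nodes)
    sub <- igraph::induced_subgraph(g, interior)
    comp <- igraph::components(sub)
    for (ni in seq_along(nodes)) {
      u <- nodes[ni]
      nb <- as.integer(igraph::neighbors(g, u))
      total <- 0L
      # direct node-node edges contribute 1 per edge
      total <- total + sum(nb %in% nodes)
      # branch interiors adjacent to u
      touched <- unique(comp$membership[match(intersect(nb, interior), interior)])
      for (cid in touched) {
        members <- interior[comp$membership == cid]
        total <- total + length(members)
        # far-end nodes of this interior: nodes adjacent to the component
        far <- unique(unlist(lapply(members, function(m) {
          as.integer(igraph::neighbors(g, m))
        })))
        far <- setdiff(intersect(far, nodes), u)
        total <- total + length(far)
      }
      cum[ni] <- total
    }
  }
  list(node_count = length(nodes), node_degrees = cum)
}

# Pairwise-ordering AUC: fraction of positive/negative pairs ranked
# correctly, ties counted one half.
oracle_auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# Exact permutation p-value by exhaustive enumeration of all equal-size
# relabelings (p = proportion of relabelings with statistic >= observed).
oracle_perm_exact <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  combs <- utils::combn(length(pool), nx)
  stats_ <- apply(combs, 2, function(idx) {
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  mean(stats_ >= obs - 1e-12)
}

# O(n^3) average-linkage agglomeration, tracking merge heights.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
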