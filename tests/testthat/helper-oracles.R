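# Independent brute-force oracles. These reimplement the checked
# operations with the simplest possible data structures and algorithms,
# sharing no code with the package internals.

# all-pairs shortest paths by Floyd-Warshall on the edge graph
oracle_floyd_warshall <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  D <- matrix(Inf, nv, nv)
  diag(D) <- 0
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  for (r in seq_len(nrow(e))) {
    len <- sqrt(sum((v[e[r, 1], ] - v[e[r, 2], ])^2))
    D[e[r, 1], e[r, 2]] <- min(D[e[r, 1], e[r, 2]], len)
    D[e[r, 2], e[r, 1]] <- D[e[r, 1], e[r, 2]]
  }
  for (k in seq_len(nv)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# naive single-source Dijkstra with linear scans (no heap, no igraph)
oracle_dijkstra <- function(adj, wts, src) {
  nv <- length(adj)
  dist <- rep(Inf, nv)
  done <- rep(FALSE, nv)
  dist[src] <- 0
  repeat {
    u <- NA
    best <- Inf
    for (i in seq_len(nv)) if (!done[i] && dist[i] < best) { best <- dist[i]; u <- i }
    if (is.na(u)) break
    done[u] <- TRUE
    for (k in seq_along(adj[[u]])) {
      vtx <- adj[[u]][k]
      alt <- dist[u] + wts[[u]][k]
      if (alt < dist[vtx]) dist[vtx] <- alt
    }
  }
  dist
}

oracle_adjacency <- function(mesh) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)],
                    f[, 2:1], f[, 3:2], f[, c(1, 3)]))
  adj <- vector("list", nv)
  wts <- vector("list", nv)
  for (r in seq_len(nrow(e))) {
    a <- e[r, 1]; b <- e[r, 2]
    if (!(b %in% adj[[a]])) {
      adj[[a]] <- c(adj[[a]], b)
      wts[[a]] <- c(wts[[a]], sqrt(sum((mesh$vertices[a, ] - mesh$vertices[b, ])^2)))
    }
  }
  list(adj = adj, wts = wts)
}

# Brute-force filtered watershed. Same semantics as the specification:
# flood in decreasing depth (ties: lower index, handled as plateaus);
# seed where no labelled neighbour; at multi-basin contacts test each
# shallower basin against the deepest adjacent one with R < thr AND
# D < thd (D recomputed from scratch by naive Dijkstra each time);
# afterwards iteratively merge basins below the area threshold into the
# longest-boundary neighbour (ties: deeper pit, then lower label).
# Labels are rewritten eagerly on every merge; no union-find.
oracle_watershed <- function(mesh, depth, thr, thd, tha) {
  nv <- length(depth)
  aw <- oracle_adjacency(mesh)
  adj <- aw$adj
  av <- vertex_areas(mesh)
  label <- integer(nv)
  pit <- integer(0)
  pdep <- numeric(0)

  if (length(unique(depth)) == 1L) {
    return(list(labels = rep(1L, nv), pits = which.max(depth)))
  }

  seed_basin <- function(v) {
    pit <<- c(pit, v)
    pdep <<- c(pdep, depth[v])
    label[v] <<- length(pit)
  }
  handle <- function(v) {
    nb_labs <- sort(unique(label[adj[[v]]][label[adj[[v]]] > 0L]))
    if (length(nb_labs) == 0L) { seed_basin(v); return(invisible()) }
    ord <- nb_labs[order(-pdep[nb_labs], pit[nb_labs])]
    target <- ord[1]
    for (b in ord[-1]) {
      r_h <- pdep[b] - depth[v]
      d_pp <- oracle_dijkstra(adj, aw$wts, pit[target])[pit[b]]
      if (r_h < thr && d_pp < thd) {
        label[label == b] <<- target   # eager relabel; target keeps deeper pit
        pdep[b] <<- -Inf               # retire basin id b
      }
    }
    label[v] <<- target
    invisible()
  }

  ord <- order(-depth, seq_len(nv))
  i <- 1
  while (i <= nv) {
    j <- i
    while (j < nv && depth[ord[j + 1]] == depth[ord[i]]) j <- j + 1
    grp <- sort(ord[i:j])
    if (length(grp) == 1L) {
      handle(grp)
    } else {
      rest <- grp
      repeat {
        hit <- rest[sapply(rest, function(v) any(label[adj[[v]]] > 0L))]
        if (length(hit) == 0L) break
        for (v in hit) handle(v)
        rest <- setdiff(rest, hit)
        if (length(rest) == 0L) break
      }
      while (length(rest) > 0L) {
        s <- rest[1]
        seed_basin(s)
        # flood the whole tied component from s
        comp <- s
        repeat {
          add <- setdiff(unique(unlist(adj[comp])), comp)
          add <- add[add %in% rest]
          if (length(add) == 0L) break
          comp <- c(comp, add)
        }
        label[comp] <- label[s]
        rest <- setdiff(rest, comp)
      }
    }
    i <- j + 1
  }

  # area filtering, recomputing everything by full scans
  repeat {
    ids <- sort(unique(label))
    areas <- sapply(ids, function(b) sum(av[label == b]))
    small <- ids[areas < tha]
    if (length(small) == 0L || length(ids) <= 1L) break
    b <- small[order(areas[match(small, ids)], small)][1]
    # boundary lengths of b against each neighbour
    blen <- list()
    f <- mesh$faces
    eds <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
    for (r in seq_len(nrow(eds))) {
      l1 <- label[eds[r, 1]]; l2 <- label[eds[r, 2]]
      if (l1 != l2 && (l1 == b || l2 == b)) {
        o <- as.character(if (l1 == b) l2 else l1)
        w <- sqrt(sum((mesh$vertices[eds[r, 1], ] - mesh$vertices[eds[r, 2], ])^2))
        blen[[o]] <- (if (is.null(blen[[o]])) 0 else blen[[o]]) + w
      }
    }
    cand <- as.integer(names(blen))
    lens <- unlist(blen)
    tgt <- cand[order(-lens, -pdep[cand], pit[cand])][1]
    if (pdep[b] > pdep[tgt] || (pdep[b] == pdep[tgt] && pit[b] < pit[tgt])) {
      pit[tgt] <- pit[b]; pdep[tgt] <- pdep[b]
    }
    label[label == b] <- tgt
  }

  ids <- sort(unique(label))
  ids <- ids[order(-pdep[ids], pit[ids])]
  list(labels = match(label, ids), pits = pit[ids])
}

# hand-coded Benjamini-Hochberg step-up with explicit family size
oracle_bh <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in seq(n, 1)) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# paired t statistic, from first principles
oracle_paired_t <- function(L, R) {
  d <- L - R
  mean(d) / (sd(d) / sqrt(length(d)))
}

# exact heat diffusion by dense generalized eigendecomposition
oracle_heat_expm <- function(mesh, texture, t_total) {
  ops <- laplace_operators(mesh)
  m <- Matrix::diag(ops$mass)
  A <- diag(1 / sqrt(m)) %*% as.matrix(ops$stiffness) %*% diag(1 / sqrt(m))
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  y <- sqrt(m) * texture
  y_t <- eig$vectors %*% (exp(-eig$values * t_total) * crossprod(eig$vectors, y))
  as.vector(y_t) / sqrt(m)
}
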