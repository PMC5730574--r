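# Structured, mirror-symmetric tetrahedral meshing of the cell dome. A
# half-disk (y >= 0) is triangulated ring by ring, mirrored about the x axis,
# extruded through the dome height in layers, and each prism is split into
# three tetrahedra using the global-index diagonal rule (conforming across
# prisms; the node numbering keeps the mesh exactly mirror-symmetric).

# half-disk triangulation: returns list(points = n x 2, tris = m x 3 CCW)
half_disk_mesh <- function(R, n_rings) {
  pts <- matrix(c(0, 0), 1, 2)
  ring_ids <- list(1L)  # node ids per ring, ordered by angle 0..pi
  for (i in seq_len(n_rings)) {
    m <- 3 * i  # segments; m + 1 points from 0 to pi inclusive
    th <- pi * (0:m) / m
    ids <- nrow(pts) + seq_len(m + 1)
    pts <- rbind(pts, cbind(R * i / n_rings * cos(th), R * i / n_rings * sin(th)))
    ring_ids[[i + 1]] <- ids
  }
  tris <- list()
  # centre fan
  r1 <- ring_ids[[2]]
  for (j in seq_len(length(r1) - 1)) tris[[length(tris) + 1]] <- c(1L, r1[j], r1[j + 1])
  # annulus zippers
  for (i in 2:n_rings) {
    A <- ring_ids[[i]]; B <- ring_ids[[i + 1]]
    ang <- function(ids) atan2(pts[ids, 2], pts[ids, 1])
    aa <- ang(A); bb <- ang(B)
    ia <- 1L; ib <- 1L
    while (ia < length(A) || ib < length(B)) {
      adv_b <- ib < length(B) && (ia == length(A) || bb[ib + 1] <= aa[ia + 1] + 1e-12)
      if (adv_b) {
        tris[[length(tris) + 1]] <- c(A[ia], B[ib], B[ib + 1])
        ib <- ib + 1L
      } else {
        tris[[length(tris) + 1]] <- c(A[ia], B[ib], A[ia + 1])
        ia <- ia + 1L
      }
    }
  }
  list(points = pts, tris = do.call(rbind, tris))
}

# full mirror-symmetric disk mesh. Node numbering: first the y = 0 nodes (in
# the order they appear in the half mesh), then y > 0 nodes, then their
# mirror images in the same order, so reflection is an order-preserving map
# on each block and the sorted-index prism split mirrors exactly.
disk_mesh <- function(R, n_rings) {
  hm <- half_disk_mesh(R, n_rings)
  p <- hm$points
  on_axis <- abs(p[, 2]) < 1e-9
  up <- which(!on_axis)
  ax <- which(on_axis)
  new_id <- integer(nrow(p))
  new_id[ax] <- seq_along(ax)
  new_id[up] <- length(ax) + seq_along(up)
  n_up <- length(up)
  mirror_id <- integer(nrow(p))           # image of each half-mesh node
  mirror_id[ax] <- new_id[ax]
  mirror_id[up] <- length(ax) + n_up + seq_along(up)
  pts <- matrix(0, length(ax) + 2 * n_up, 2)
  pts[new_id[ax], ] <- p[ax, , drop = FALSE]
  pts[new_id[up], ] <- p[up, , drop = FALSE]
  pts[mirror_id[up], ] <- cbind(p[up, 1], -p[up, 2])
  t_up <- cbind(new_id[hm$tris[, 1]], new_id[hm$tris[, 2]], new_id[hm$tris[, 3]])
  t_dn <- cbind(mirror_id[hm$tris[, 1]], mirror_id[hm$tris[, 3]], mirror_id[hm$tris[, 2]])
  list(points = pts, tris = rbind(t_up, t_dn))
}

# split a prism (bottom b1 b2 b3, top t1 t2 t3 above them) into 3 tets using
# the sorted-global-index rule; conforming across shared quad faces
prism_to_tets <- function(bot, top) {
  o <- order(bot)
  b <- bot[o]; t <- top[o]
  rbind(c(b[1], b[2], b[3], t[1]),
        c(b[2], b[3], t[1], t[2]),
        c(b[3], t[1], t[2], t[3]))
}

tet_volume_signed <- function(nodes, tet) {
  a <- nodes[tet[1], ]; b <- nodes[tet[2], ]; cc <- nodes[tet[3], ]; d <- nodes[tet[4], ]
  u <- b - a; v <- cc - a; w <- d - a
  (u[1] * (v[2] * w[3] - v[3] * w[2]) - u[2] * (v[1] * w[3] - v[3] * w[1]) +
     u[3] * (v[1] * w[2] - v[2] * w[1])) / 6
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  u <- nodes[tets[, 2], , drop = FALSE] - a
  v <- nodes[tets[, 3], , drop = FALSE] - a
  w <- nodes[tets[, 4], , drop = FALSE] - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' Mesh the cell model
#'
#' Builds a conforming tetrahedral mesh of the dome (boundary-fitted: surface
#' nodes lie exactly on the dome), labels elements as nucleus or cytoplasm by
#' centroid, snaps focal-adhesion centres to distinct basal nodes, and
#' discretizes the fiber polylines into 3-node beam elements whose nodes are
#' tied to the enclosing solid elements by interpolation (fiber ends directly
#' to their ACAFA patch node).
#'
#' @param model A `cell_model` from [build_cell_geometry()].
#' @param mesh_h Target in-plane element size (um); default from the config.
#' @param tet_order `"linear"` or `"quadratic"`; default from the config.
#' @return A `fem_mesh` list: `nodes`, `tets` (4 or 10 columns), `tet_phase`,
#'   `basal_nodes`, `fa` (tibble with node-set list-column), `beam_nodes`,
#'   `beam_elems`, `beam_fiber`, `ties`, `corner_nodes` count, plus the
#'   model.
#' @export
mesh_cell <- function(model, mesh_h = NULL, tet_order = NULL) {
  check_that(inherits(model, "cell_model"), "model", "must be a cell_model")
  if (is.null(mesh_h)) mesh_h <- model$mesh_h
  if (is.null(tet_order)) tet_order <- model$tet_order
  check_that(mesh_h > 0, "mesh_h", "must be > 0")
  R <- model$cell_radius
  n_rings <- max(4L, ceiling(R / mesh_h))
  dm <- disk_mesh(R, n_rings)
  n2d <- nrow(dm$points)
  nl <- model$n_layers
  rr <- sqrt(dm$points[, 1]^2 + dm$points[, 2]^2)
  hcol <- dome_height(model, rr)
  nodes <- do.call(rbind, lapply(0:nl, function(k) {
    cbind(dm$points[, 1], dm$points[, 2], hcol * k / nl)
  }))
  layer_id <- function(k) k * n2d  # offset for layer k (0-based)
  tets <- vector("list", nl * nrow(dm$tris))
  idx <- 0L
  for (k in 0:(nl - 1)) {
    ob <- layer_id(k); ot <- layer_id(k + 1)
    for (tri in seq_len(nrow(dm$tris))) {
      idx <- idx + 1L
      tets[[idx]] <- prism_to_tets(dm$tris[tri, ] + ob, dm$tris[tri, ] + ot)
    }
  }
  tets <- do.call(rbind, tets)
  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  vol <- abs(vol)
  keep <- vol > 1e-12
  tets <- tets[keep, , drop = FALSE]; vol <- vol[keep]
  cent <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] +
             nodes[tets[, 4], ]) / 4
  phase <- ifelse(in_nucleus(model, cent), "nucleus", "cytoplasm")
  basal <- which(abs(nodes[, 3]) < 1e-9)
  # snap FA centres to distinct basal nodes
  fa <- model$fa
  bxy <- nodes[basal, 1:2, drop = FALSE]
  taken <- integer(0)
  snap <- integer(nrow(fa))
  for (i in seq_len(nrow(fa))) {
    d2 <- (bxy[, 1] - fa$x[i])^2 + (bxy[, 2] - fa$y[i])^2
    ord <- order(d2)
    ord <- ord[!(basal[ord] %in% taken)]
    snap[i] <- basal[ord[1]]
    taken <- c(taken, snap[i])
  }
  # patch node sets: basal nodes inside the FA footprint, plus the snapped
  # node; contested nodes go to the nearest FA centre
  owner <- rep(0L, length(basal))
  bestd <- rep(Inf, length(basal))
  for (i in seq_len(nrow(fa))) {
    dx <- bxy[, 1] - fa$x[i]; dy <- bxy[, 2] - fa$y[i]
    ca <- cos(fa$angle[i]); sa <- sin(fa$angle[i])
    u <- ca * dx + sa * dy; v <- -sa * dx + ca * dy
    inside <- (u / fa$semi_major[i])^2 + (v / fa$semi_minor[i])^2 <= 1
    d2 <- dx^2 + dy^2
    upd <- inside & d2 < bestd
    owner[upd] <- i
    bestd[upd] <- d2[upd]
  }
  owner[match(snap, basal)] <- seq_len(nrow(fa))
  fa$snap_node <- snap
  fa$node_set <- lapply(seq_len(nrow(fa)), function(i) sort(unique(c(basal[owner == i], snap[i]))))
  # beams: resample each fiber polyline at ~mesh_h/2 spacing, odd node count
  beam_nodes <- matrix(0, 0, 3)
  beam_elems <- matrix(0L, 0, 3)
  beam_fiber <- integer(0)
  tie_end_node <- list()
  for (fi in seq_along(model$fibers)) {
    pl <- model$fibers[[fi]]
    seg <- sqrt(rowSums(diff(pl)^2))
    s <- c(0, cumsum(seg))
    n_el <- max(4L, ceiling(s[length(s)] / mesh_h))
    n_nd <- 2L * n_el + 1L
    ss <- seq(0, s[length(s)], length.out = n_nd)
    px <- stats::approx(s, pl[, 1], ss)$y
    py <- stats::approx(s, pl[, 2], ss)$y
    pz <- stats::approx(s, pl[, 3], ss)$y
    ids <- nrow(beam_nodes) + seq_len(n_nd)
    beam_nodes <- rbind(beam_nodes, cbind(px, py, pz))
    el <- cbind(ids[seq(1, n_nd - 2, by = 2)], ids[seq(2, n_nd - 1, by = 2)],
                ids[seq(3, n_nd, by = 2)])
    beam_elems <- rbind(beam_elems, el)
    beam_fiber <- c(beam_fiber, rep(fi, nrow(el)))
    # fiber ends tie to their ACAFA patch nodes
    nf <- model$n_fibers
    tie_end_node[[length(tie_end_node) + 1]] <- list(beam_node = ids[1],
                                                     fa_row = model$n_cfa + fi)
    tie_end_node[[length(tie_end_node) + 1]] <- list(beam_node = ids[n_nd],
                                                     fa_row = model$n_cfa + nf + fi)
  }
  mesh <- list(nodes = nodes, tets = tets, tet_phase = phase, tet_vol = vol,
               basal_nodes = basal, fa = fa,
               beam_nodes = beam_nodes, beam_elems = beam_elems,
               beam_fiber = beam_fiber, tie_end = tie_end_node,
               n_rings = n_rings, model = model, tet_order = tet_order)
  if (identical(model$nucleus_coupling, "normal")) mesh <- split_nucleus_interface(mesh)
  if (tet_order == "quadratic") mesh <- add_midside_nodes(mesh)
  if (identical(model$nucleus_coupling, "normal")) mesh <- pair_interface_nodes(mesh)
  mesh$ties <- build_beam_ties(mesh)
  class(mesh) <- "fem_mesh"
  mesh
}

# duplicate the nodes shared by nucleus and cytoplasm elements so the two
# regions meet at coincident but distinct nodes; the nucleus side gets the
# new copies. This prepares the linearized frictionless interface (normal
# coupling, free tangential slip).
split_nucleus_interface <- function(mesh) {
  nuc <- mesh$tet_phase == "nucleus"
  n_nodes_nuc <- unique(as.vector(mesh$tets[nuc, , drop = FALSE]))
  n_nodes_cyt <- unique(as.vector(mesh$tets[!nuc, , drop = FALSE]))
  shared <- intersect(n_nodes_nuc, n_nodes_cyt)
  if (!length(shared)) return(mesh)
  map <- integer(nrow(mesh$nodes))
  map[shared] <- nrow(mesh$nodes) + seq_along(shared)
  mesh$nodes <- rbind(mesh$nodes, mesh$nodes[shared, , drop = FALSE])
  tn <- mesh$tets[nuc, , drop = FALSE]
  repl <- map[tn] > 0
  tn[repl] <- map[tn[repl]]
  mesh$tets[nuc, ] <- tn
  # duplicated basal nodes keep the basal out-of-plane restraint
  add_basal <- map[intersect(shared, mesh$basal_nodes)]
  mesh$basal_nodes <- sort(c(mesh$basal_nodes, add_basal))
  mesh
}

# outward unit normal of the nucleus ellipsoid at points (n x 3)
nucleus_normals <- function(model, pts) {
  a <- model$nucleus_semi_axes; ctr <- model$nucleus_center
  g <- cbind((pts[, 1] - ctr[1]) / a[1]^2, (pts[, 2] - ctr[2]) / a[2]^2,
             (pts[, 3] - ctr[3]) / a[3]^2)
  g / sqrt(rowSums(g^2))
}

# pair coincident nodes across the split interface (corners and, for
# quadratic meshes, midside nodes) and attach interface normals
pair_interface_nodes <- function(mesh) {
  key <- paste(round(mesh$nodes[, 1], 6), round(mesh$nodes[, 2], 6),
               round(mesh$nodes[, 3], 6))
  dupgrp <- split(seq_len(nrow(mesh$nodes)), key)
  dupgrp <- dupgrp[lengths(dupgrp) == 2]
  if (!length(dupgrp)) { mesh$interface_pairs <- NULL; return(mesh) }
  prs <- do.call(rbind, dupgrp)
  nrm <- nucleus_normals(mesh$model, mesh$nodes[prs[, 1], , drop = FALSE])
  mesh$interface_pairs <- list(a = prs[, 1], b = prs[, 2], normal = nrm)
  mesh
}

# promote the 4-node mesh to 10-node tets by inserting unique midside nodes;
# column order: corners 1-4 then edges (1,2),(2,3),(3,1),(1,4),(2,4),(3,4)
add_midside_nodes <- function(mesh) {
  tets <- mesh$tets
  edges <- rbind(tets[, c(1, 2)], tets[, c(2, 3)], tets[, c(3, 1)],
                 tets[, c(1, 4)], tets[, c(2, 4)], tets[, c(3, 4)])
  lo <- pmin(edges[, 1], edges[, 2]); hi <- pmax(edges[, 1], edges[, 2])
  key <- lo + hi * (nrow(mesh$nodes) + 1)
  ukey <- unique(key)
  mid_id <- nrow(mesh$nodes) + match(key, ukey)
  first <- match(ukey, key)
  mids <- (mesh$nodes[lo[first], , drop = FALSE] +
             mesh$nodes[hi[first], , drop = FALSE]) / 2
  mesh$corner_nodes <- nrow(mesh$nodes)
  mesh$nodes <- rbind(mesh$nodes, mids)
  ne <- nrow(tets)
  mesh$tets <- cbind(tets, matrix(mid_id, ne, 6))
  mesh
}

# barycentric coordinates of point p w.r.t. tet corners (4 x 3)
tet_bary <- function(corners, p) {
  Tm <- t(corners[2:4, , drop = FALSE]) - corners[1, ]
  rhs <- p - corners[1, ]
  lam <- tryCatch(solve(Tm, rhs), error = function(e) rep(NA_real_, 3))
  c(1 - sum(lam), lam)
}

# 10-node tet shape functions at barycentric coords L (length 4); node order
# as in add_midside_nodes
tet10_shape <- function(L) {
  c(L[1] * (2 * L[1] - 1), L[2] * (2 * L[2] - 1), L[3] * (2 * L[3] - 1),
    L[4] * (2 * L[4] - 1),
    4 * L[1] * L[2], 4 * L[2] * L[3], 4 * L[3] * L[1],
    4 * L[1] * L[4], 4 * L[2] * L[4], 4 * L[3] * L[4])
}

# interpolation ties: for every beam node, the solid nodes and weights that
# reproduce the solid displacement at that point; fiber ends tie rigidly to
# their ACAFA snapped node
build_beam_ties <- function(mesh) {
  if (nrow(mesh$beam_nodes) == 0) return(list())
  corners <- mesh$tets[, 1:4, drop = FALSE]
  c1 <- mesh$nodes[corners[, 1], , drop = FALSE]
  # bounding boxes for candidate filtering
  xs <- matrix(mesh$nodes[corners, 1], ncol = 4)
  ys <- matrix(mesh$nodes[corners, 2], ncol = 4)
  zs <- matrix(mesh$nodes[corners, 3], ncol = 4)
  bb <- cbind(apply(xs, 1, min), apply(xs, 1, max), apply(ys, 1, min),
              apply(ys, 1, max), apply(zs, 1, min), apply(zs, 1, max))
  end_rows <- vapply(mesh$tie_end, function(e) e$beam_node, integer(1))
  ties <- vector("list", nrow(mesh$beam_nodes))
  for (bn in seq_len(nrow(mesh$beam_nodes))) {
    if (bn %in% end_rows) {
      e <- mesh$tie_end[[match(bn, end_rows)]]
      ties[[bn]] <- list(nodes = mesh$fa$snap_node[e$fa_row], w = 1)
      next
    }
    p <- mesh$beam_nodes[bn, ]
    tol <- 1e-6
    cand <- which(p[1] >= bb[, 1] - tol & p[1] <= bb[, 2] + tol &
                    p[2] >= bb[, 3] - tol & p[2] <= bb[, 4] + tol &
                    p[3] >= bb[, 5] - tol & p[3] <= bb[, 6] + tol)
    best <- NULL; best_min <- -Inf
    for (e in cand) {
      lam <- tet_bary(mesh$nodes[corners[e, ], , drop = FALSE], p)
      if (any(is.na(lam))) next
      m <- min(lam)
      if (m > best_min) { best_min <- m; best <- list(e = e, lam = lam) }
      if (m >= -1e-9) break
    }
    if (is.null(best)) {
      abort(sprintf("beam node %d at (%.2f, %.2f, %.2f) lies outside the solid mesh",
                    bn, p[1], p[2], p[3]), class = "nucmorph_geometry_error")
    }
    lam <- pmax(best$lam, 0); lam <- lam / sum(lam)  # clamp tiny negatives
    if (mesh$tet_order == "quadratic") {
      ties[[bn]] <- list(nodes = mesh$tets[best$e, ], w = tet10_shape(lam))
    } else {
      ties[[bn]] <- list(nodes = corners[best$e, ], w = lam)
    }
  }
  ties
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("<fem_mesh> %d nodes, %d %s tets (%d nucleus), %d beam elements, %d FAs\n",
              nrow(x$nodes), nrow(x$tets),
              if (x$tet_order == "quadratic") "10-node" else "4-node",
              sum(x$tet_phase == "nucleus"), nrow(x$beam_elems), nrow(x$fa)))
  invisible(x)
}

# region volumes of the meshed phases (for convergence checks)
mesh_phase_volumes <- function(mesh) {
  tapply(mesh$tet_vol, mesh$tet_phase, sum)
}
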