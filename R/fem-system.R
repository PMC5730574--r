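# Global assembly, boundary conditions, static solve and post-processing.
# Master DOFs are the solid translations (3 per mesh node) plus beam-node
# rotations (3 per beam node); beam-node translations are slaved to the
# solid displacement field by interpolation (tie constraints), expressed
# through a sparse transformation matrix T with u_full = T u_master.

#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve
NULL

fiber_section <- function(model) {
  r <- model$fiber_radius
  A <- pi * r^2
  I <- pi * r^4 / 4
  m <- model$materials$fiber
  list(E = m$E, G = m$E / (2 * (1 + m$nu)), A = A, I = I, J = 2 * I,
       kappa = model$kappa)
}

# assemble the solid stiffness as triplets (element loop in R; the element
# matrices are small and the loop is the dominant cost at desk scale)
assemble_solid <- function(mesh) {
  model <- mesh$model
  npe <- if (mesh$tet_order == "quadratic") 10L else 4L
  ne <- nrow(mesh$tets)
  mats <- list(cytoplasm = model$materials$cytoplasm,
               nucleus = model$materials$nucleus)
  Ds <- lapply(mats, function(m) elastic_D(m$E, m$nu))
  nd <- 3L * npe
  Kes <- matrix(0, nd * nd, ne)
  for (e in seq_len(ne)) {
    nn <- mesh$tets[e, ]
    Ke <- tet_stiffness_D(mesh$nodes[nn, , drop = FALSE], Ds[[mesh$tet_phase[e]]])
    Kes[, e] <- Ke
  }
  edof <- t(apply(mesh$tets, 1, function(nn) rep(3L * (nn - 1L), each = 3L) + rep(1:3, npe)))
  ii <- edof[, rep(seq_len(nd), times = nd), drop = FALSE]
  jj <- edof[, rep(seq_len(nd), each = nd), drop = FALSE]
  ns <- 3L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = as.vector(t(ii)), j = as.vector(t(jj)),
                       x = as.vector(Kes), dims = c(ns, ns), repr = "C")
}

# internal: tet stiffness with a precomputed D matrix
tet_stiffness_D <- function(corners, D) {
  g <- tet_geometry(corners[1:4, , drop = FALSE])
  if (nrow(corners) == 4) {
    B <- strain_B(g$grads)
    return(g$vol * crossprod(B, D %*% B))
  }
  K <- matrix(0, 30, 30)
  for (q in 1:4) {
    B <- strain_B(tet10_dshape(tet4pt[q, ], g$grads))
    K <- K + (g$vol / 4) * crossprod(B, D %*% B)
  }
  K
}

# full-space beam stiffness triplets (beam DOFs live after the solid DOFs:
# beam node j has 6 full DOFs starting at 3*n_nodes + 6*(j-1))
assemble_beams <- function(mesh) {
  ns <- 3L * nrow(mesh$nodes)
  nb <- nrow(mesh$beam_nodes)
  nfull <- ns + 6L * nb
  if (nb == 0 || nrow(mesh$beam_elems) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nfull, nfull)))
  }
  sec <- fiber_section(mesh$model)
  ii <- list(); jj <- list(); xx <- list()
  for (e in seq_len(nrow(mesh$beam_elems))) {
    nn <- mesh$beam_elems[e, ]
    for (s in 1:2) {
      n1 <- nn[s]; n2 <- nn[s + 1]
      Ke <- beam2_global(mesh$beam_nodes[n1, ], mesh$beam_nodes[n2, ],
                         sec$E, sec$G, sec$A, sec$I, sec$kappa, sec$J)
      dof <- c(ns + 6L * (n1 - 1L) + 1:6, ns + 6L * (n2 - 1L) + 1:6)
      ii[[length(ii) + 1]] <- rep(dof, times = 12)
      jj[[length(jj) + 1]] <- rep(dof, each = 12)
      xx[[length(xx) + 1]] <- as.vector(Ke)
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nfull, nfull))
}

# penalty across the split nucleus-cytoplasm interface: active pairs
# exchange tractions along the ellipsoid normal only (frictionless contact,
# linearized kinematics); a tiny all-direction regularization spring keeps
# the floating nucleus from acquiring exact rigid modes when pairs release
assemble_interface_penalty <- function(mesh, k_c, active = NULL, k_reg = 1) {
  ns <- 3L * nrow(mesh$nodes)
  ip <- mesh$interface_pairs
  if (is.null(ip)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(ns, ns)))
  }
  if (is.null(active)) active <- rep(TRUE, length(ip$a))
  ii <- list(); jj <- list(); xx <- list()
  for (q in seq_along(ip$a)) {
    n <- ip$normal[q, ]
    Kn <- (if (active[q]) k_c else 0) * tcrossprod(n) + k_reg * diag(3)
    dofs <- c(3L * (ip$a[q] - 1L) + 1:3, 3L * (ip$b[q] - 1L) + 1:3)
    Kp <- rbind(cbind(Kn, -Kn), cbind(-Kn, Kn))
    ii[[q]] <- rep(dofs, times = 6)
    jj[[q]] <- rep(dofs, each = 6)
    xx[[q]] <- as.vector(Kp)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(ns, ns))
}

# sparse tie transformation u_full = T u_master.
#   "tied": every beam-node translation is slaved to the interpolated solid
#           displacement; masters are solid DOFs + beam rotations.
#   "normal"/"ends": only fiber-end translations are slaved (to their ACAFA
#           node); interior beam translations stay master DOFs.
tie_transform <- function(mesh, coupling) {
  ns <- 3L * nrow(mesh$nodes)
  nb <- nrow(mesh$beam_nodes)
  nfull <- ns + 6L * nb
  end_rows <- vapply(mesh$tie_end, function(e) e$beam_node, integer(1))
  slave <- if (coupling == "tied") seq_len(nb) else end_rows
  ii <- list(seq_len(ns)); jj <- list(seq_len(ns)); xx <- list(rep(1, ns))
  # master numbering: solid DOFs first, then per beam node its non-slaved
  # translations (3) and rotations (3) in order
  master_of <- integer(nfull)
  master_of[seq_len(ns)] <- seq_len(ns)
  nm <- ns
  for (j in seq_len(nb)) {
    base <- ns + 6L * (j - 1L)
    if (!(j %in% slave)) {
      for (d in 1:3) {
        nm <- nm + 1L
        master_of[base + d] <- nm
        ii[[length(ii) + 1]] <- base + d
        jj[[length(jj) + 1]] <- nm
        xx[[length(xx) + 1]] <- 1
      }
    }
    for (d in 4:6) {
      nm <- nm + 1L
      master_of[base + d] <- nm
      ii[[length(ii) + 1]] <- base + d
      jj[[length(jj) + 1]] <- nm
      xx[[length(xx) + 1]] <- 1
    }
  }
  for (j in slave) {
    tie <- mesh$ties[[j]]
    base <- ns + 6L * (j - 1L)
    for (d in 1:3) {
      ii[[length(ii) + 1]] <- rep(base + d, length(tie$nodes))
      jj[[length(jj) + 1]] <- 3L * (tie$nodes - 1L) + d
      xx[[length(xx) + 1]] <- tie$w
    }
  }
  Tt <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                             dims = c(nfull, nm))
  list(T = Tt, master_of = master_of, n_master = nm)
}

# unit tangents at beam nodes (central differences along each fiber)
beam_tangents <- function(mesh) {
  tg <- matrix(0, nrow(mesh$beam_nodes), 3)
  for (el in seq_len(nrow(mesh$beam_elems))) {
    nn <- mesh$beam_elems[el, ]
    for (k in 1:3) {
      lo <- if (k == 1) nn[1] else nn[k - 1]
      hi <- if (k == 3) nn[3] else nn[k + 1]
      d <- mesh$beam_nodes[hi, ] - mesh$beam_nodes[lo, ]
      tg[nn[k], ] <- d / sqrt(sum(d^2))
    }
  }
  tg
}

# contact direction for each interior beam node: the upward direction in the
# plane normal to the fiber tangent (the taut fiber presses the material
# beneath it along this axis; lateral slip and axial slip are free)
beam_contact_dirs <- function(mesh) {
  tg <- beam_tangents(mesh)
  m <- cbind(-tg[, 1] * tg[, 3], -tg[, 2] * tg[, 3], 1 - tg[, 3]^2)
  nz <- sqrt(rowSums(m^2))
  bad <- nz < 1e-6  # vertical tangent: fall back to +x in the normal plane
  if (any(bad)) {
    m[bad, ] <- cbind(1 - tg[bad, 1]^2, -tg[bad, 1] * tg[bad, 2],
                      -tg[bad, 1] * tg[bad, 3])
    nz[bad] <- sqrt(rowSums(m[bad, , drop = FALSE]^2))
  }
  m / nz
}

# unilateral penalty coupling of interior beam nodes to the interpolated
# solid displacement along the contact direction (active pairs only);
# fiber-solid contact is frictionless so the tangential components are free
assemble_normal_penalty <- function(mesh, k_n, active = NULL) {
  ns <- 3L * nrow(mesh$nodes)
  nb <- nrow(mesh$beam_nodes)
  nfull <- ns + 6L * nb
  end_rows <- vapply(mesh$tie_end, function(e) e$beam_node, integer(1))
  dirs <- beam_contact_dirs(mesh)
  inner <- setdiff(seq_len(nb), end_rows)
  if (is.null(active)) active <- rep(TRUE, nb)
  ii <- list(); jj <- list(); xx <- list()
  for (j in inner) {
    if (!active[j]) next
    tie <- mesh$ties[[j]]
    P <- tcrossprod(dirs[j, ])
    dofs <- c(ns + 6L * (j - 1L) + 1:3,
              as.vector(vapply(as.integer(tie$nodes),
                               function(n) 3L * (n - 1L) + 1:3, integer(3))))
    coef <- c(1, -tie$w)
    nbk <- length(coef)
    Kp <- k_n * (outer(coef, coef) %x% P)
    ii[[length(ii) + 1]] <- rep(dofs, times = nbk * 3)
    jj[[length(jj) + 1]] <- rep(dofs, each = nbk * 3)
    xx[[length(xx) + 1]] <- as.vector(Kp)
  }
  if (!length(ii)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nfull, nfull)))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nfull, nfull))
}

#' Prescribed-stretch boundary conditions
#'
#' At every focal-adhesion node: longitudinal displacement `u_x = strain * x`
#' (x measured from the cell centroid) is prescribed, transverse in-plane
#' motion is free, and out-of-plane motion is blocked. All other basal nodes
#' are blocked out-of-plane only. One central basal node is pinned in y to
#' remove the in-plane rigid mode, and fiber end rotations are clamped
#' (focal-adhesion plaques anchor the fiber ends).
#'
#' @param mesh A `fem_mesh`.
#' @param strain Applied strain (default from the model config).
#' @return List with `idx` (solid DOF indices; DOF `3(n-1)+d` is direction
#'   `d` of node `n`) and `val` (prescribed values).
#' @export
apply_stretch_bc <- function(mesh, strain = NULL) {
  model <- mesh$model
  if (is.null(strain)) strain <- model$applied_strain
  fa_nodes <- sort(unique(unlist(mesh$fa$node_set)))
  if (!length(fa_nodes)) abort("no focal-adhesion nodes in mesh",
                               class = "nucmorph_fem_error")
  idx <- c(3L * (fa_nodes - 1L) + 1L,                 # u_x at FAs
           3L * (mesh$basal_nodes - 1L) + 3L)         # u_z on basal plane
  val <- c(strain * mesh$nodes[fa_nodes, 1], rep(0, length(mesh$basal_nodes)))
  # pin u_y at the basal node nearest the centroid
  ctr <- mesh$basal_nodes[which.min(rowSums(mesh$nodes[mesh$basal_nodes, 1:2]^2))]
  idx <- c(idx, 3L * (ctr - 1L) + 2L)
  val <- c(val, 0)
  dup <- !duplicated(idx)
  list(idx = idx[dup], val = val[dup])
}

#' Solve the stretched-cell model
#'
#' Assembles the three-phase system (solid tetrahedra, tied beams), applies
#' the prescribed-stretch boundary conditions and solves the static problem
#' with a direct sparse factorization. Reactions are recovered at the
#' constrained DOFs.
#'
#' @param mesh A `fem_mesh` (from [mesh_cell()]).
#' @param with_cap Include the actin-cap beams (default from the model
#'   config).
#' @param strain Applied stretch strain (default from the model config).
#' @return A `cell_fem_solution`: displacements (`n x 3`), beam rotations,
#'   reactions at constrained DOFs, relative residual, strain energy.
#' @export
solve_cell_fem <- function(mesh, with_cap = NULL, strain = NULL,
                           max_contact_iter = 30L) {
  check_that(inherits(mesh, "fem_mesh"), "mesh", "must be a fem_mesh")
  model <- mesh$model
  if (is.null(with_cap)) with_cap <- model$with_cap
  Ks0 <- mesh$K_solid
  if (is.null(Ks0)) Ks0 <- assemble_solid(mesh)
  ns <- 3L * nrow(mesh$nodes)
  nb <- if (with_cap) nrow(mesh$beam_nodes) else 0L
  coupling <- model$fiber_coupling
  if (is.null(coupling)) coupling <- "normal"
  bc <- apply_stretch_bc(mesh, strain = strain)
  tinfo <- NULL; Kb <- NULL; dirs <- NULL
  if (with_cap && nb > 0) {
    Kb <- assemble_beams(mesh)
    tinfo <- tie_transform(mesh, coupling)
    # clamp fiber-end rotations (FA plaques anchor the fiber ends)
    ends <- vapply(mesh$tie_end, function(e) e$beam_node, integer(1))
    rot <- as.vector(vapply(ends, function(b) {
      tinfo$master_of[ns + 6L * (b - 1L) + 4:6]
    }, integer(3)))
    bc$idx <- c(bc$idx, rot)
    bc$val <- c(bc$val, rep(0, length(rot)))
    if (coupling == "normal") dirs <- beam_contact_dirs(mesh)
  }
  ip <- mesh$interface_pairs
  act_int <- if (!is.null(ip)) rep(TRUE, length(ip$a)) else logical(0)
  act_fib <- rep(TRUE, nrow(mesh$beam_nodes))
  iterate_int <- !is.null(ip)
  iterate_fib <- with_cap && nb > 0 && coupling == "normal"
  tol <- 1e-9
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Ks <- Ks0
    if (!is.null(ip)) {
      Ks <- Ks + assemble_interface_penalty(mesh, model$interface_normal_penalty,
                                            active = act_int)
    }
    if (with_cap && nb > 0) {
      Kfull <- Matrix::bdiag(Ks, Matrix::Matrix(0, 6L * nb, 6L * nb, sparse = TRUE)) + Kb
      if (coupling == "normal") {
        Kfull <- Kfull + assemble_normal_penalty(mesh, model$fiber_normal_penalty,
                                                 active = act_fib)
      }
      Km <- Matrix::crossprod(tinfo$T, Kfull %*% tinfo$T)
    } else {
      Km <- Ks
    }
    Km <- (Km + Matrix::t(Km)) / 2
    nm <- nrow(Km)
    free <- setdiff(seq_len(nm), bc$idx)
    u <- numeric(nm)
    u[bc$idx] <- bc$val
    Kff <- Km[free, free, drop = FALSE]
    rhs <- -Km[free, bc$idx, drop = FALSE] %*% bc$val
    uf <- tryCatch(Matrix::solve(Kff, rhs),
                   error = function(e) {
                     abort(paste0("singular stiffness system (unconstrained rigid-body ",
                                  "mode?): ", conditionMessage(e)),
                           class = "nucmorph_fem_error")
                   })
    u[free] <- as.numeric(uf)
    # contact update: release pairs that would transmit tension, re-engage
    # pairs that would interpenetrate
    changed <- FALSE
    usolid <- matrix(u[seq_len(ns)], ncol = 3, byrow = TRUE)
    if (iterate_int) {
      du <- usolid[ip$b, , drop = FALSE] - usolid[ip$a, , drop = FALSE]
      s <- rowSums(du * ip$normal)
      new_int <- s >= -tol
      if (any(new_int != act_int)) { act_int <- new_int; changed <- TRUE }
    }
    if (iterate_fib) {
      ufull <- as.numeric(tinfo$T %*% u)
      ubeam <- matrix(ufull[ns + seq_len(6 * nb)], ncol = 6, byrow = TRUE)
      end_rows <- vapply(mesh$tie_end, function(e) e$beam_node, integer(1))
      s <- vapply(seq_len(nb), function(j) {
        if (j %in% end_rows) return(0)
        tie <- mesh$ties[[j]]
        usol <- colSums(tie$w * usolid[as.integer(tie$nodes), , drop = FALSE])
        sum((ubeam[j, 1:3] - usol) * dirs[j, ])
      }, numeric(1))
      new_fib <- s <= tol
      if (any(new_fib != act_fib)) { act_fib <- new_fib; changed <- TRUE }
    }
    if (!changed || iter >= max_contact_iter) break
  }
  res <- sqrt(sum((Kff %*% uf - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-30)
  reactions_all <- as.numeric(Km %*% u)
  energy <- 0.5 * sum(u * reactions_all)
  reac <- numeric(nm)
  reac[bc$idx] <- reactions_all[bc$idx]
  beam_disp <- NULL
  if (with_cap && nb > 0) {
    ufull <- as.numeric(tinfo$T %*% u)
    beam_disp <- matrix(ufull[ns + seq_len(6 * nb)], ncol = 6, byrow = TRUE)
    colnames(beam_disp) <- c("ux", "uy", "uz", "rx", "ry", "rz")
  }
  structure(list(
    contact_iterations = iter,
    interface_active = if (iterate_int) act_int else NULL,
    fiber_active = if (iterate_fib) act_fib else NULL,
    u_master = u,
    displacements = matrix(u[seq_len(ns)], ncol = 3, byrow = TRUE),
    beam_motion = beam_disp,
    reactions = reac, prescribed = bc, residual = res,
    strain_energy = energy, with_cap = with_cap && nb > 0,
    strain = if (is.null(strain)) model$applied_strain else strain,
    mesh = mesh), class = "cell_fem_solution")
}

#' @export
print.cell_fem_solution <- function(x, ...) {
  cat(sprintf("<cell_fem_solution> %s cap, strain %.3g, residual %.2e, energy %.4g pN um\n",
              if (x$with_cap) "with" else "without", x$strain, x$residual,
              x$strain_energy))
  invisible(x)
}

#' Per-focal-adhesion reaction forces
#'
#' Sums the nodal reactions over each focal adhesion's patch and reports the
#' resultant vector, magnitude, class and radial position, plus the class
#' force fractions (percent of total reaction-force magnitude).
#'
#' @param solution A `cell_fem_solution`.
#' @return An `fa_force_report` tibble (one row per FA) with attribute
#'   `class_fractions`.
#' @export
fa_reaction_report <- function(solution) {
  mesh <- solution$mesh
  reac <- solution$reactions
  rows <- purrr::map_dfr(seq_len(nrow(mesh$fa)), function(i) {
    nn <- mesh$fa$node_set[[i]]
    fx <- sum(reac[3 * (nn - 1) + 1])
    fy <- sum(reac[3 * (nn - 1) + 2])
    fz <- sum(reac[3 * (nn - 1) + 3])
    tibble::tibble(id = mesh$fa$id[i], class = mesh$fa$class[i],
                   x = mesh$nodes[mesh$fa$snap_node[i], 1],
                   y = mesh$nodes[mesh$fa$snap_node[i], 2],
                   radial_position = sqrt(sum(mesh$nodes[mesh$fa$snap_node[i], 1:2]^2)),
                   fx = fx, fy = fy, fz = fz,
                   fmag = sqrt(fx^2 + fy^2 + fz^2))
  })
  total <- sum(rows$fmag)
  fr <- rows |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(force = sum(.data$fmag), .groups = "drop") |>
    dplyr::mutate(fraction_pct = 100 * .data$force / total)
  structure(rows, class_fractions = fr,
            class = c("fa_force_report", class(rows)))
}

#' Nuclear von Mises stress statistics
#'
#' Computes the element stress tensor (at the centroid for linear elements,
#' averaged over the Gauss points for quadratic), takes the von Mises
#' invariant, and summarizes over nucleus elements both volume-weighted and
#' unweighted (element-average) forms.
#'
#' @param solution A `cell_fem_solution`.
#' @return One-row tibble: `mean_vm`, `median_vm`, `p95_vm` (volume-weighted,
#'   Pa), `mean_vm_unweighted`, `n_elements`.
#' @export
nuclear_stress_report <- function(solution) {
  vm <- element_von_mises(solution)
  mesh <- solution$mesh
  sel <- mesh$tet_phase == "nucleus"
  w <- mesh$tet_vol[sel] / sum(mesh$tet_vol[sel])
  v <- vm[sel]
  ord <- order(v)
  cw <- cumsum(w[ord])
  qw <- function(p) v[ord][which(cw >= p)[1]]
  tibble::tibble(mean_vm = sum(w * v), median_vm = qw(0.5), p95_vm = qw(0.95),
                 mean_vm_unweighted = mean(v), n_elements = sum(sel))
}

# von Mises stress per element
element_von_mises <- function(solution) {
  mesh <- solution$mesh
  model <- mesh$model
  npe <- if (mesh$tet_order == "quadratic") 10L else 4L
  Ds <- list(cytoplasm = elastic_D(model$materials$cytoplasm$E, model$materials$cytoplasm$nu),
             nucleus = elastic_D(model$materials$nucleus$E, model$materials$nucleus$nu))
  u <- t(solution$displacements)
  vm <- numeric(nrow(mesh$tets))
  for (e in seq_len(nrow(mesh$tets))) {
    nn <- mesh$tets[e, ]
    ue <- as.vector(u[, nn])
    g <- tet_geometry(mesh$nodes[nn[1:4], , drop = FALSE])
    D <- Ds[[mesh$tet_phase[e]]]
    sig <- if (npe == 4) {
      D %*% (strain_B(g$grads) %*% ue)
    } else {
      s <- numeric(6)
      for (q in 1:4) s <- s + D %*% (strain_B(tet10_dshape(tet4pt[q, ], g$grads)) %*% ue)
      s / 4
    }
    vm[e] <- von_mises(sig)
  }
  vm
}

# von Mises invariant from Voigt stress (xx, yy, zz, xy, yz, zx)
von_mises <- function(s) {
  sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 + (s[3] - s[1])^2) +
         3 * (s[4]^2 + s[5]^2 + s[6]^2))
}

#' Compare the stretched cell with and without the actin cap
#'
#' Solves the identical continuum mesh twice, once with the seven cap beams
#' tied in and once without (all 56 focal adhesions retained in both), and
#' reports the change in the conventional-FA share of total reaction force
#' and in mean nuclear von Mises stress.
#'
#' @param config A [cell_model_config()] (or `cell_model`).
#' @param mesh_h,tet_order Optional mesh overrides.
#' @return A `cap_comparison` list; see [tidy.cap_comparison()].
#' @export
compare_cap <- function(config, mesh_h = NULL, tet_order = NULL) {
  model <- if (inherits(config, "cell_model")) config else build_cell_geometry(config)
  mesh <- mesh_cell(model, mesh_h = mesh_h, tet_order = tet_order)
  mesh$K_solid <- assemble_solid(mesh)
  sol_with <- solve_cell_fem(mesh, with_cap = TRUE)
  sol_without <- solve_cell_fem(mesh, with_cap = FALSE)
  fa_w <- fa_reaction_report(sol_with)
  fa_wo <- fa_reaction_report(sol_without)
  cfrac <- function(rep) {
    fr <- attr(rep, "class_fractions")
    fr$fraction_pct[fr$class == "CFA"]
  }
  ns_w <- nuclear_stress_report(sol_with)
  ns_wo <- nuclear_stress_report(sol_without)
  out <- list(
    fa_with = fa_w, fa_without = fa_wo,
    nuclear_with = ns_w, nuclear_without = ns_wo,
    cfa_fraction_with = cfrac(fa_w), cfa_fraction_without = cfrac(fa_wo),
    cfa_reduction_pct = 100 * (cfrac(fa_wo) - cfrac(fa_w)) / cfrac(fa_wo),
    stress_with = ns_w$mean_vm, stress_without = ns_wo$mean_vm,
    stress_reduction_pct = 100 * (ns_wo$mean_vm - ns_w$mean_vm) / ns_wo$mean_vm,
    solution_with = sol_with, solution_without = sol_without)
  class(out) <- "cap_comparison"
  out
}

#' @export
print.cap_comparison <- function(x, ...) {
  cat("<cap_comparison>\n")
  cat(sprintf("  CFA force share: %.1f%% (no cap) -> %.1f%% (cap); reduction %.1f%%\n",
              x$cfa_fraction_without, x$cfa_fraction_with, x$cfa_reduction_pct))
  cat(sprintf("  mean nuclear von Mises: %.3g Pa (no cap) -> %.3g Pa (cap); reduction %.1f%%\n",
              x$stress_without, x$stress_with, x$stress_reduction_pct))
  invisible(x)
}

#' Tidy a cap comparison
#'
#' @param x A `cap_comparison`.
#' @param ... Unused.
#' @return Tibble with one row per reported quantity.
#' @export
tidy.cap_comparison <- function(x, ...) {
  tibble::tibble(
    quantity = c("cfa_force_fraction_pct", "mean_nuclear_von_mises_pa"),
    without_cap = c(x$cfa_fraction_without, x$stress_without),
    with_cap = c(x$cfa_fraction_with, x$stress_with),
    reduction_pct = c(x$cfa_reduction_pct, x$stress_reduction_pct))
}

#' One-row summary of a cap comparison
#'
#' @param x A `cap_comparison`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.cap_comparison <- function(x, ...) {
  tibble::tibble(cfa_reduction_pct = x$cfa_reduction_pct,
                 stress_reduction_pct = x$stress_reduction_pct,
                 residual_with = x$solution_with$residual,
                 residual_without = x$solution_without$residual)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
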