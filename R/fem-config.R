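#' Configuration of the adherent-cell finite-element model
#'
#' Parametric three-phase model of an adherent fibroblast-like cell: a
#' flattened-dome cytoplasm, an ellipsoidal nucleus, and (optionally) seven
#' perinuclear actin-cap fibers modeled as shear-deformable beams arching
#' over the nucleus between opposed peripheral focal adhesions. 42 circular
#' conventional focal adhesions (CFAs, 2.3 um^2 each) are uniformly
#' distributed on the basal plane and 14 elliptical actin-cap-associated
#' focal adhesions (ACAFAs, 4 x 1 um axes) sit in two opposed peripheral
#' sectors; each fiber terminates in an opposed ACAFA pair.
#'
#' Material defaults are literature-range values for fibroblasts (they are
#' this package's defaults, not measured properties): cytoplasm E = 1 kPa,
#' nucleus E = 5 kPa (both nu = 0.37), fiber E = 1.45 MPa, nu = 0.3, circular
#' cross-section of radius 0.2 um, shear correction kappa = 0.9. Lengths are
#' in micrometres and moduli in pascals, so forces come out in piconewtons.
#'
#' @param cell_radius Cell radius (um).
#' @param cell_height `c(peripheral, apex)` dome heights (um); the dome
#'   profile is `h(r) = hp + (ha - hp) (1 - (r/R)^2)`.
#' @param nucleus_semi_axes `c(a, b, c)` nucleus semi-axes (um).
#' @param nucleus_center Nucleus centre (um); the default rests the nucleus
#'   on the basal plane with its apex at the dome apex.
#' @param n_cfa Number of conventional focal adhesions.
#' @param cfa_area CFA area (um^2).
#' @param acafa_axes `c(major, minor)` ACAFA ellipse axis lengths (um).
#' @param acafa_radius Radial position of ACAFA centres (um).
#' @param n_fibers Number of actin-cap fibers (one ACAFA pair each).
#' @param fiber_sector_half_angle Half-angle (degrees) of the two peripheral
#'   ACAFA sectors, centred on the +x and -x directions.
#' @param fiber_radius Fiber cross-section radius (um).
#' @param materials Named list `cytoplasm`, `nucleus`, `fiber`, each a list
#'   with `E` (Pa) and `nu`.
#' @param kappa Timoshenko shear correction factor.
#' @param applied_strain Prescribed stretch strain at the focal adhesions
#'   (0.08 = 8%).
#' @param fiber_coupling How the fiber body interacts with the surrounding
#'   solid: `"tied"` (default) bonds the beam nodes to the solid displacement
#'   field (fully embedded fiber); `"normal"` is unilateral frictionless
#'   contact -- the fiber slides freely along its own tangent and presses
#'   (never pulls) the material beneath it, resolved by active-set
#'   iteration; `"ends"` leaves the fiber body free so only the end ties
#'   act. Fiber ends are always tied to their ACAFA.
#' @param fiber_normal_penalty Contact penalty stiffness (pN/um per beam
#'   node) for `"normal"` coupling.
#' @param nucleus_coupling Nucleus-cytoplasm interface: `"tied"` (default)
#'   bonds the interface into one continuum; `"normal"` duplicates the
#'   interface nodes and transmits compressive surface-normal tractions only
#'   (unilateral frictionless contact, active-set iteration) so the nucleus
#'   sits unbonded in its pocket.
#' @param interface_normal_penalty Contact penalty stiffness (pN/um per
#'   interface node pair) for the `"normal"` interface.
#' @param with_cap Include the cap fibers?
#' @param mesh_h Target in-plane mesh size (um).
#' @param n_layers Number of vertical element layers.
#' @param tet_order `"linear"` (4-node) or `"quadratic"` (10-node)
#'   tetrahedra.
#' @return A `cell_model_config` list.
#' @export
cell_model_config <- function(cell_radius = 25,
                              cell_height = c(peripheral = 2, apex = 6),
                              nucleus_semi_axes = c(8, 6, 3),
                              nucleus_center = c(0, 0, 3),
                              n_cfa = 42L,
                              cfa_area = 2.3,
                              acafa_axes = c(4, 1),
                              acafa_radius = NULL,
                              n_fibers = 7L,
                              fiber_sector_half_angle = 15,
                              fiber_radius = 0.2,
                              materials = list(
                                cytoplasm = list(E = 1000, nu = 0.37),
                                nucleus = list(E = 5000, nu = 0.37),
                                fiber = list(E = 1.45e6, nu = 0.3)),
                              kappa = 0.9,
                              applied_strain = 0.08,
                              fiber_coupling = c("tied", "normal", "ends"),
                              fiber_normal_penalty = 1e5,
                              nucleus_coupling = c("tied", "normal"),
                              interface_normal_penalty = 1e5,
                              with_cap = TRUE,
                              mesh_h = 2,
                              n_layers = 4L,
                              tet_order = c("linear", "quadratic")) {
  tet_order <- match.arg(tet_order)
  fiber_coupling <- match.arg(fiber_coupling)
  nucleus_coupling <- match.arg(nucleus_coupling)
  check_that(fiber_normal_penalty > 0, "fiber_normal_penalty", "must be > 0")
  check_that(interface_normal_penalty > 0, "interface_normal_penalty", "must be > 0")
  check_that(cell_radius > 0, "cell_radius", "must be > 0")
  check_that(length(cell_height) == 2 && all(cell_height > 0) &&
               cell_height[2] >= cell_height[1],
             "cell_height", "must be c(peripheral, apex) with apex >= peripheral > 0")
  check_that(length(nucleus_semi_axes) == 3 && all(nucleus_semi_axes > 0),
             "nucleus_semi_axes", "must be 3 positive semi-axes")
  check_that(length(nucleus_center) == 3, "nucleus_center", "must be length 3")
  check_that(n_cfa >= 1, "n_cfa", "must be >= 1")
  check_that(cfa_area > 0, "cfa_area", "must be > 0")
  check_that(length(acafa_axes) == 2 && all(acafa_axes > 0), "acafa_axes",
             "must be c(major, minor) > 0")
  check_that(n_fibers >= 1, "n_fibers", "must be >= 1")
  check_that(fiber_radius > 0, "fiber_radius", "must be > 0")
  for (ph in c("cytoplasm", "nucleus", "fiber")) {
    m <- materials[[ph]]
    check_that(!is.null(m) && m$E > 0 && m$nu >= 0 && m$nu < 0.5,
               sprintf("materials$%s", ph), "needs E > 0 and 0 <= nu < 0.5")
  }
  check_that(kappa > 0, "kappa", "must be > 0")
  check_that(applied_strain >= 0, "applied_strain", "must be >= 0")
  check_that(mesh_h > 0, "mesh_h", "must be > 0")
  check_that(n_layers >= 2, "n_layers", "must be >= 2")
  if (is.null(acafa_radius)) acafa_radius <- cell_radius - 3
  # nucleus containment: strictly inside laterally, inside [0, h] vertically
  a <- nucleus_semi_axes[1]; b <- nucleus_semi_axes[2]; cz <- nucleus_semi_axes[3]
  ctr <- nucleus_center
  check_that(sqrt((abs(ctr[1]) + a)^2 + 0) < cell_radius &&
               (abs(ctr[2]) + b) < cell_radius,
             "nucleus_semi_axes", "nucleus must be laterally inside the cell")
  check_that(ctr[3] - cz >= -1e-9, "nucleus_center",
             "nucleus must not cross the basal plane")
  hp <- cell_height[1]; ha <- cell_height[2]
  hh <- function(r) hp + (ha - hp) * (1 - (r / cell_radius)^2)
  # sample the nucleus top against the dome
  ths <- seq(0, 2 * pi, length.out = 73)[-73]
  for (s in seq(0, 1, by = 0.1)) {
    px <- ctr[1] + a * s * cos(ths); py <- ctr[2] + b * s * sin(ths)
    zt <- ctr[3] + cz * sqrt(pmax(1 - s^2, 0))
    check_that(all(zt <= hh(sqrt(px^2 + py^2)) + 1e-6), "nucleus_center",
               "nucleus must fit under the dome")
  }
  structure(list(cell_radius = cell_radius,
                 cell_height = stats::setNames(as.numeric(cell_height),
                                               c("peripheral", "apex")),
                 nucleus_semi_axes = as.numeric(nucleus_semi_axes),
                 nucleus_center = as.numeric(nucleus_center),
                 n_cfa = as.integer(n_cfa), cfa_area = cfa_area,
                 acafa_axes = as.numeric(acafa_axes), acafa_radius = acafa_radius,
                 n_fibers = as.integer(n_fibers),
                 fiber_sector_half_angle = fiber_sector_half_angle,
                 fiber_radius = fiber_radius, materials = materials,
                 kappa = kappa, applied_strain = applied_strain,
                 fiber_coupling = fiber_coupling,
                 fiber_normal_penalty = fiber_normal_penalty,
                 nucleus_coupling = nucleus_coupling,
                 interface_normal_penalty = interface_normal_penalty,
                 with_cap = isTRUE(with_cap), mesh_h = mesh_h,
                 n_layers = as.integer(n_layers), tet_order = tet_order),
            class = "cell_model_config")
}

# dome height at radius r
dome_height <- function(config, r) {
  hp <- config$cell_height[["peripheral"]]; ha <- config$cell_height[["apex"]]
  hp + (ha - hp) * pmax(1 - (r / config$cell_radius)^2, 0)
}

# z of the nucleus top surface above (x, y); 0 outside the footprint
nucleus_top <- function(config, x, y) {
  a <- config$nucleus_semi_axes[1]; b <- config$nucleus_semi_axes[2]
  cz <- config$nucleus_semi_axes[3]; ctr <- config$nucleus_center
  s2 <- ((x - ctr[1]) / a)^2 + ((y - ctr[2]) / b)^2
  ifelse(s2 < 1, ctr[3] + cz * sqrt(pmax(1 - s2, 0)), 0)
}

in_nucleus <- function(config, pts) {
  a <- config$nucleus_semi_axes[1]; b <- config$nucleus_semi_axes[2]
  cz <- config$nucleus_semi_axes[3]; ctr <- config$nucleus_center
  ((pts[, 1] - ctr[1]) / a)^2 + ((pts[, 2] - ctr[2]) / b)^2 +
    ((pts[, 3] - ctr[3]) / cz)^2 <= 1
}

#' Build the cell geometry: focal-adhesion layout and fiber paths
#'
#' CFA centres are placed by a deterministic sunflower (Fibonacci-disk)
#' packing over the basal disk, excluding the two peripheral ACAFA sectors;
#' ACAFAs are fanned evenly across the two opposed sectors; each fiber runs
#' from an ACAFA up over the apical surface of the nucleus (which the cap
#' hugs) and down to the diametrically opposed ACAFA.
#'
#' @param config A [cell_model_config()].
#' @return A `cell_model`: the config plus `fa` (tibble: id, class, x, y,
#'   radius/axes, angle) and `fibers` (list of `n x 3` polyline matrices,
#'   um).
#' @export
build_cell_geometry <- function(config) {
  check_that(inherits(config, "cell_model_config"), "config",
             "must be a cell_model_config")
  R <- config$cell_radius
  half <- deg2rad(config$fiber_sector_half_angle)
  cfa_r <- sqrt(config$cfa_area / pi)
  # ACAFAs: n_fibers per sector, fanned evenly, mirrored at +x / -x
  nf <- config$n_fibers
  fan <- if (nf == 1) 0 else seq(-half, half, length.out = nf)
  aca_ang <- c(fan, fan + pi)
  aca <- tibble::tibble(
    id = paste0("ACAFA_", seq_along(aca_ang)),
    class = "ACAFA",
    x = config$acafa_radius * cos(aca_ang),
    y = config$acafa_radius * sin(aca_ang),
    angle = aca_ang,                      # ellipse major axis toward centre
    semi_major = config$acafa_axes[1] / 2,
    semi_minor = config$acafa_axes[2] / 2)
  # CFAs: sunflower packing, rejecting points in the ACAFA sector annulus
  golden <- pi * (3 - sqrt(5))
  r_max <- R - 2 * cfa_r
  n_need <- config$n_cfa
  sector_block_r <- config$acafa_radius - config$acafa_axes[1]
  sunflower <- function(ntot) {
    i <- seq_len(ntot)
    rr <- r_max * sqrt((i - 0.5) / ntot)
    th <- i * golden
    px <- rr * cos(th); py <- rr * sin(th)
    ang <- atan2(py, px)
    in_sector <- (abs(ang) < half + 0.1 | abs(ang) > pi - half - 0.1) &
      rr > sector_block_r
    cbind(px, py)[!in_sector, , drop = FALSE]
  }
  # grow the packing until enough points survive the sector rejection, then
  # keep an evenly spaced subset (preserves the uniform radial density)
  pts <- NULL
  for (ntot in n_need:(4 * n_need)) {
    cand <- sunflower(ntot)
    if (nrow(cand) >= n_need) {
      keep <- round(seq(1, nrow(cand), length.out = n_need))
      pts <- cand[keep, , drop = FALSE]
      break
    }
  }
  check_that(!is.null(pts) && nrow(pts) == n_need, "n_cfa", "could not place all CFAs")
  cfa <- tibble::tibble(id = paste0("CFA_", seq_len(n_need)), class = "CFA",
                        x = pts[, 1], y = pts[, 2], angle = 0,
                        semi_major = cfa_r, semi_minor = cfa_r)
  fa <- dplyr::bind_rows(cfa, aca)
  # overlap audit: directional ellipse radius toward the other FA centre
  dir_radius <- function(i, phi) {
    psi <- phi - fa$angle[i]
    a1 <- fa$semi_major[i]; b1 <- fa$semi_minor[i]
    a1 * b1 / sqrt((b1 * cos(psi))^2 + (a1 * sin(psi))^2)
  }
  for (i in seq_len(nrow(fa) - 1)) for (j in (i + 1):nrow(fa)) {
    dx <- fa$x[j] - fa$x[i]; dy <- fa$y[j] - fa$y[i]
    d <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    if (d < dir_radius(i, phi) + dir_radius(j, phi)) {
      abort(sprintf("focal-adhesion regions %s and %s overlap", fa$id[i], fa$id[j]),
            class = "nucmorph_geometry_error")
    }
  }
  # fiber polylines: plan-view straight between opposed ACAFAs, hugging the
  # nucleus apical surface with a short ramp at each end
  fibers <- lapply(seq_len(nf), function(i) {
    A <- c(aca$x[i], aca$y[i])
    B <- c(aca$x[i + nf], aca$y[i + nf])
    tt <- seq(0, 1, length.out = 41)
    px <- A[1] + tt * (B[1] - A[1])
    py <- A[2] + tt * (B[2] - A[2])
    rr <- sqrt(px^2 + py^2)
    env <- pmin(pmax(nucleus_top(config, px, py) + 0.3, 0.25),
                dome_height(config, rr) * 0.98)
    ramp <- pmin(1, tt / 0.12, (1 - tt) / 0.12)
    pz <- env * ramp
    pz[c(1, length(tt))] <- 0
    cbind(x = px, y = py, z = pz)
  })
  structure(c(unclass(config), list(fa = fa, fibers = fibers)),
            class = c("cell_model", "cell_model_config"))
}
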