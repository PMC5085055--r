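## Axisymmetric total-Lagrangian finite-element engine.
##
## 4-node bilinear quadrilaterals in the (r, z) half-plane, hoop stretch
## 1 + u_r/R, selective reduced integration: the deviatoric part of the energy
## is integrated with the 2x2 Gauss rule, the volumetric penalty at the element
## centroid only. This keeps the pure-displacement formulation free of
## volumetric locking at near-incompressibility while the residual and
## stiffness stay exact derivatives of the discrete energy, so the Newton
## tangent is consistent to machine precision.
##
## Pressure loads are follower loads: they act on the deformed edge geometry
## and contribute an (unsymmetric) load-stiffness term.

gauss2 <- 1 / sqrt(3)
quad_pts <- rbind(
  c(-gauss2, -gauss2), c(gauss2, -gauss2),
  c(gauss2, gauss2), c(-gauss2, gauss2),
  c(0, 0) # centroid, weight 4, used for the volumetric term
)
quad_wts <- c(1, 1, 1, 1, 4)

shape_fun <- function(xi, eta) {
  c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
    (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
}
shape_der <- function(xi, eta) {
  # 4 x 2: dN/dxi, dN/deta
  cbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
        c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
}

#' Load case for the static solver
#'
#' @param internal_pressure Uniform pressure (MPa) applied to the posterior
#'   (wetted) surface of the cornea; the IOP at one instant. Must be >= 0.
#' @param external_pressure_field `NULL`, or a function of the reference
#'   meridional radius (mm) returning pressure in MPa, applied to the anterior
#'   surface; the air pulse at one instant.
#' @return Object of class `load_case`.
#' @export
load_case <- function(internal_pressure = 0, external_pressure_field = NULL) {
  stopifnot(length(internal_pressure) == 1L, internal_pressure >= 0)
  if (!is.null(external_pressure_field)) stopifnot(is.function(external_pressure_field))
  structure(list(internal_pressure = internal_pressure,
                 external_pressure_field = external_pressure_field),
            class = "load_case")
}

# ---------------------------------------------------------------------------
# Problem assembly container
# ---------------------------------------------------------------------------

# nodes: n x 2 (r, z); elem: nel x 4 counterclockwise connectivity;
# c10/c01/kappa: per-element material vectors; fixed_dofs/fixed_vals:
# Dirichlet data at full load (ramped); edge_loads: list of
# list(edges = m x 2 node ids, p = per-edge pressure at full load).
# Positive pressure pushes along the normal obtained by rotating the
# edge tangent (node1 -> node2) by -90 degrees in the (r, z) plane.
fe_problem <- function(nodes, elem, c10, c01, kappa,
                       fixed_dofs = integer(), fixed_vals = NULL,
                       edge_loads = list()) {
  nel <- nrow(elem)
  nnode <- nrow(nodes)
  ndof <- 2L * nnode
  if (is.null(fixed_vals)) fixed_vals <- numeric(length(fixed_dofs))
  stopifnot(length(fixed_dofs) == length(fixed_vals),
            length(c10) == nel, length(c01) == nel, length(kappa) == nel)

  edof <- matrix(0L, nel, 8L)
  for (a in 1:4) {
    edof[, 2L * a - 1L] <- 2L * elem[, a] - 1L
    edof[, 2L * a] <- 2L * elem[, a]
  }

  rr <- matrix(nodes[elem, 1L], nel, 4L)
  zz <- matrix(nodes[elem, 2L], nel, 4L)
  quad <- vector("list", 5L)
  for (g in 1:5) {
    dNxi <- shape_der(quad_pts[g, 1L], quad_pts[g, 2L])
    N <- shape_fun(quad_pts[g, 1L], quad_pts[g, 2L])
    J11 <- rr %*% dNxi[, 1L]; J12 <- rr %*% dNxi[, 2L]
    J21 <- zz %*% dNxi[, 1L]; J22 <- zz %*% dNxi[, 2L]
    detJ <- as.vector(J11 * J22 - J12 * J21)
    if (any(detJ <= 0)) stop("mesh has non-positive element Jacobians", call. = FALSE)
    dNdR <- matrix(0, nel, 4L); dNdZ <- matrix(0, nel, 4L)
    for (a in 1:4) {
      dNdR[, a] <- (dNxi[a, 1L] * J22 - dNxi[a, 2L] * J21) / detJ
      dNdZ[, a] <- (-dNxi[a, 1L] * J12 + dNxi[a, 2L] * J11) / detJ
    }
    Rg <- as.vector(rr %*% N)
    quad[[g]] <- list(dNdR = dNdR, dNdZ = dNdZ, N = N, R = Rg,
                      w0 = quad_wts[g] * detJ * 2 * pi * Rg)
  }

  free_dofs <- setdiff(seq_len(ndof), fixed_dofs)
  list(nodes = nodes, elem = elem, nel = nel, nnode = nnode, ndof = ndof,
       c10 = c10, c01 = c01, kappa = kappa, edof = edof,
       rr = rr, zz = zz, quad = quad,
       fixed_dofs = as.integer(fixed_dofs), fixed_vals = fixed_vals,
       free_dofs = free_dofs, edge_loads = edge_loads)
}

# Kinematics at one quadrature point for all elements: returns list with the
# deformation-gradient components, hoop stretch and Voigt C matrix (nel x 4).
fe_kinematics <- function(pb, g, ure, uze) {
  q <- pb$quad[[g]]
  F11 <- 1 + rowSums(q$dNdR * ure); F12 <- rowSums(q$dNdZ * ure)
  F21 <- rowSums(q$dNdR * uze);     F22 <- 1 + rowSums(q$dNdZ * uze)
  lth <- 1 + as.vector(ure %*% q$N) / q$R
  cm <- cbind(F11^2 + F21^2, F12^2 + F22^2, lth^2, F11 * F12 + F21 * F22)
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22, lth = lth, cm = cm)
}

# B operator: dC/du as nel x 4 x 8 array
fe_bmatrix <- function(pb, g, kin) {
  q <- pb$quad[[g]]
  nel <- pb$nel
  B <- array(0, dim = c(nel, 4L, 8L))
  for (a in 1:4) {
    ir <- 2L * a - 1L; iz <- 2L * a
    B[, 1L, ir] <- 2 * q$dNdR[, a] * kin$F11
    B[, 1L, iz] <- 2 * q$dNdR[, a] * kin$F21
    B[, 2L, ir] <- 2 * q$dNdZ[, a] * kin$F12
    B[, 2L, iz] <- 2 * q$dNdZ[, a] * kin$F22
    B[, 3L, ir] <- 2 * kin$lth * q$N[a] / q$R
    B[, 4L, ir] <- q$dNdR[, a] * kin$F12 + q$dNdZ[, a] * kin$F11
    B[, 4L, iz] <- q$dNdR[, a] * kin$F22 + q$dNdZ[, a] * kin$F21
  }
  B
}

# Internal force, optionally stiffness triplet values (nel x 8 x 8) and energy
fe_internal <- function(pb, u, need_K = FALSE, need_energy = FALSE) {
  nel <- pb$nel
  ur <- u[seq(1L, pb$ndof, by = 2L)]
  uz <- u[seq(2L, pb$ndof, by = 2L)]
  ure <- matrix(ur[pb$elem], nel, 4L)
  uze <- matrix(uz[pb$elem], nel, 4L)

  fe <- matrix(0, nel, 8L)
  Ke <- if (need_K) array(0, dim = c(nel, 8L, 8L)) else NULL
  energy <- 0

  for (g in 1:5) {
    part <- if (g == 5L) "vol" else "dev"
    q <- pb$quad[[g]]
    kin <- fe_kinematics(pb, g, ure, uze)
    if (any(!is.finite(kin$cm)) || any(kin$cm[, 1:3] <= 0)) {
      return(list(ok = FALSE))
    }
    gr <- mr_gradient_c(kin$cm, pb$c10, pb$c01, pb$kappa, part = part)
    if (any(!is.finite(gr))) return(list(ok = FALSE))
    B <- fe_bmatrix(pb, g, kin)
    for (k in 1:4) fe <- fe + (q$w0 * gr[, k]) * B[, k, ]
    if (need_energy) {
      energy <- energy + sum(q$w0 * mr_energy_c(kin$cm, pb$c10, pb$c01, pb$kappa, part = part))
    }
    if (need_K) {
      H <- mr_hessian_c(kin$cm, pb$c10, pb$c01, pb$kappa, part = part)
      # material part: B' H B
      HB <- array(0, dim = c(nel, 4L, 8L))
      for (k in 1:4) for (l in 1:4) HB[, k, ] <- HB[, k, ] + H[, k, l] * B[, l, ]
      for (a in 1:8) for (k in 1:4) {
        Ke[, a, ] <- Ke[, a, ] + (q$w0 * B[, k, a]) * HB[, k, ]
      }
      # geometric part: second derivative of C contracted with dW/dc
      g1 <- gr[, 1L]; g2 <- gr[, 2L]; g3 <- gr[, 3L]; g4 <- gr[, 4L]
      for (a in 1:4) for (b in 1:4) {
        Gab <- 2 * g1 * q$dNdR[, a] * q$dNdR[, b] +
               2 * g2 * q$dNdZ[, a] * q$dNdZ[, b] +
               g4 * (q$dNdR[, a] * q$dNdZ[, b] + q$dNdZ[, a] * q$dNdR[, b])
        w <- q$w0 * Gab
        Ke[, 2L * a - 1L, 2L * b - 1L] <- Ke[, 2L * a - 1L, 2L * b - 1L] + w +
          q$w0 * 2 * g3 * q$N[a] * q$N[b] / q$R^2
        Ke[, 2L * a, 2L * b] <- Ke[, 2L * a, 2L * b] + w
      }
    }
  }

  f <- numeric(pb$ndof)
  rs <- rowsum(as.vector(fe), as.vector(pb$edof))
  f[as.integer(rownames(rs))] <- rs[, 1L]
  out <- list(ok = TRUE, f = f, energy = energy)
  if (need_K) {
    ii <- pb$edof[, rep(1:8, times = 8L)]
    jj <- pb$edof[, rep(1:8, each = 8L)]
    out$K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                                  x = as.vector(Ke),
                                  dims = c(pb$ndof, pb$ndof))
  }
  out
}

# Follower pressure on 2-node edges of an axisymmetric surface. `p` is the
# per-edge pressure (already scaled by the load factor); current coordinates.
# Exact integration of f_a = 2*pi*p * int N_a (z', -r') r dxi over the edge.
fe_follower <- function(pb, u, loads_scaled, need_K = FALSE) {
  f <- numeric(pb$ndof)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (ld in loads_scaled) {
    ed <- ld$edges
    p <- ld$p
    n1 <- ed[, 1L]; n2 <- ed[, 2L]
    r1 <- pb$nodes[n1, 1L] + u[2L * n1 - 1L]; z1 <- pb$nodes[n1, 2L] + u[2L * n1]
    r2 <- pb$nodes[n2, 1L] + u[2L * n2 - 1L]; z2 <- pb$nodes[n2, 2L] + u[2L * n2]
    s <- pi * p / 3
    A <- 2 * r1 + r2; Bc <- r1 + 2 * r2
    dz <- z2 - z1; dr <- r2 - r1
    fv <- cbind(s * A * dz, -s * A * dr, s * Bc * dz, -s * Bc * dr)
    dofs <- cbind(2L * n1 - 1L, 2L * n1, 2L * n2 - 1L, 2L * n2)
    rs <- rowsum(as.vector(fv), as.vector(dofs))
    f[as.integer(rownames(rs))] <- f[as.integer(rownames(rs))] + rs[, 1L]
    if (need_K) {
      m <- length(p)
      D <- array(0, dim = c(m, 4L, 4L)) # d f / d (r1, z1, r2, z2)
      D[, 1L, 1L] <- 2 * s * dz;        D[, 1L, 2L] <- -s * A
      D[, 1L, 3L] <- s * dz;            D[, 1L, 4L] <- s * A
      D[, 2L, 1L] <- -s * (2 * dr - A); D[, 2L, 3L] <- -s * (dr + A)
      D[, 3L, 1L] <- s * dz;            D[, 3L, 2L] <- -s * Bc
      D[, 3L, 3L] <- 2 * s * dz;        D[, 3L, 4L] <- s * Bc
      D[, 4L, 1L] <- -s * (dr - Bc);    D[, 4L, 3L] <- -s * (2 * dr + Bc)
      ii <- dofs[, rep(1:4, times = 4L)]
      jj <- dofs[, rep(1:4, each = 4L)]
      trip_i <- c(trip_i, as.vector(ii))
      trip_j <- c(trip_j, as.vector(jj))
      trip_x <- c(trip_x, as.vector(D))
    }
  }
  out <- list(f = f)
  if (need_K) {
    out$K <- if (length(trip_x)) {
      Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                           dims = c(pb$ndof, pb$ndof))
    } else {
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(pb$ndof, pb$ndof))
    }
  }
  out
}

# loads with ramp = FALSE are held at full value throughout the load stepping
# (e.g. the IOP while the air pulse ramps); ramped loads scale with lambda
scale_loads <- function(edge_loads, lambda) {
  lapply(edge_loads, function(ld) {
    fac <- if (isFALSE(ld$ramp)) 1 else lambda
    list(edges = ld$edges, p = fac * ld$p)
  })
}

# residual R = f_int - f_ext and optionally K = dR/du at load factor lambda
fe_residual <- function(pb, u, lambda, need_K = FALSE) {
  int <- fe_internal(pb, u, need_K = need_K)
  if (!int$ok) return(list(ok = FALSE))
  ext <- fe_follower(pb, u, scale_loads(pb$edge_loads, lambda), need_K = need_K)
  out <- list(ok = TRUE, R = int$f - ext$f, f_int = int$f, f_ext = ext$f)
  if (need_K) out$K <- int$K - ext$K
  out
}

#' @keywords internal
fe_newton_step <- function(pb, u, lambda, tol, max_iter = 30L) {
  free <- pb$free_dofs
  u[pb$fixed_dofs] <- lambda * pb$fixed_vals
  for (it in seq_len(max_iter)) {
    res <- fe_residual(pb, u, lambda, need_K = TRUE)
    if (!res$ok) return(list(ok = FALSE, u = u))
    Rf <- res$R[free]
    ref <- max(sqrt(sum(res$f_ext^2)), sqrt(sum(res$f_int^2)), 1e-12)
    rn <- sqrt(sum(Rf^2))
    if (rn <= tol * ref) {
      return(list(ok = TRUE, u = u, resid = rn / ref, iters = it - 1L))
    }
    Kff <- res$K[free, free, drop = FALSE]
    du <- tryCatch(as.vector(Matrix::solve(Kff, -Rf)),
                   error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) return(list(ok = FALSE, u = u))
    # backtracking safeguard: allow transient residual growth (normal for
    # full Newton far from the solution) but damp steps that blow up
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:5) {
      u_try <- u
      u_try[free] <- u[free] + alpha * du
      res2 <- fe_residual(pb, u_try, lambda, need_K = FALSE)
      if (res2$ok) {
        rn2 <- sqrt(sum(res2$R[free]^2))
        if (is.finite(rn2) && rn2 < 10 * max(rn, tol * ref)) {
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) return(list(ok = FALSE, u = u))
    u <- u_try
  }
  list(ok = FALSE, u = u)
}

# Core incremental-iterative solver. Returns class "displacement_field".
fe_solve <- function(pb, n_increments = 20L, tol = 1e-6, u0 = NULL,
                     max_halvings = 5L) {
  u <- if (is.null(u0)) numeric(pb$ndof) else u0
  lambda <- 0
  dlam <- 1 / n_increments
  halvings <- 0L
  history <- list()
  while (lambda < 1 - 1e-12) {
    target <- min(1, lambda + dlam)
    st <- fe_newton_step(pb, u, target, tol)
    if (st$ok) {
      u <- st$u
      lambda <- target
      history[[length(history) + 1L]] <- list(lambda = lambda, iters = st$iters,
                                              resid = st$resid)
      # cautiously grow the step back after success
      if (st$iters <= 5L && halvings > 0L) {
        dlam <- min(dlam * 2, 1 / n_increments)
        halvings <- halvings - 1L
      }
    } else {
      halvings <- halvings + 1L
      if (halvings > max_halvings) {
        cond <- structure(
          class = c("ap_nonconvergence", "error", "condition"),
          list(message = sprintf(
            "Newton solver failed to converge beyond load fraction %.4f", lambda),
            call = sys.call(-1), last_lambda = lambda, u = u))
        stop(cond)
      }
      dlam <- dlam / 2
    }
  }
  last <- history[[length(history)]]
  structure(list(u = matrix(u, ncol = 2L, byrow = TRUE),
                 u_flat = u, converged = TRUE,
                 residual_norm = last$resid, steps = history),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement field: %d nodes, converged = %s, scaled residual = %.3g, %d load steps\n",
              nrow(x$u), x$converged, x$residual_norm, length(x$steps)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Public solver on a cornea mesh
# ---------------------------------------------------------------------------

# Build the fe_problem for a cornea mesh: per-element material, symmetry and
# clamp boundary conditions, IOP on the wetted posterior surface and an
# optional air-pulse field on the anterior surface.
cornea_problem <- function(mesh, material, holder = linear_elastic(1500, 0.3),
                           load = load_case(), ramp_internal = TRUE) {
  hm <- elastic_as_hyper(holder)
  is_holder <- mesh$mat_id == 2L
  c10 <- ifelse(is_holder, hm$c10, material$c10)
  c01 <- ifelse(is_holder, hm$c01, material$c01)
  kappa <- ifelse(is_holder, hm$bulk_penalty, material$bulk_penalty)

  fixed <- c(2L * mesh$sets$axis_nodes - 1L,              # u_r = 0 on the axis
             2L * mesh$sets$clamped_nodes - 1L,           # outer edge fully fixed
             2L * mesh$sets$clamped_nodes)
  fixed <- sort(unique(fixed))

  edge_loads <- list()
  if (load$internal_pressure > 0) {
    ed <- mesh$sets$posterior_edges
    edge_loads[[length(edge_loads) + 1L]] <-
      list(edges = ed, p = rep(load$internal_pressure, nrow(ed)),
           ramp = ramp_internal)
  }
  if (!is.null(load$external_pressure_field)) {
    ed <- mesh$sets$anterior_edges
    rmid <- (mesh$nodes[ed[, 1L], 1L] + mesh$nodes[ed[, 2L], 1L]) / 2
    pv <- load$external_pressure_field(rmid)
    keep <- pv > 0
    if (any(keep)) {
      edge_loads[[length(edge_loads) + 1L]] <-
        list(edges = ed[keep, , drop = FALSE], p = pv[keep])
    }
  }
  fe_problem(mesh$nodes, mesh$elem, c10, c01, kappa,
             fixed_dofs = fixed, edge_loads = edge_loads)
}

#' Quasi-static nonlinear solve of the air-puff configuration
#'
#' Solves equilibrium of the cornea + holder under intraocular pressure and an
#' optional instantaneous air-pulse pressure field, by Newton iteration with
#' automatic load stepping (step halving on divergence, at most 5 halvings).
#' Pressures are follower loads. Convergence requires the scaled residual norm
#' to drop below `tol`.
#'
#' @param mesh A cornea mesh from [build_mesh()].
#' @param material [mooney_rivlin()] parameters of the cornea.
#' @param holder [linear_elastic()] parameters of the clamping ring.
#' @param load A [load_case()].
#' @param n_increments Number of load increments to full load.
#' @param tol Relative residual tolerance.
#' @param u0 Optional displacement start vector (length `2 * n_nodes`,
#'   interleaved r/z) for warm starts.
#' @return A `displacement_field`: per-node displacements `u` (mm, columns
#'   `u_r`, `u_z`), convergence flag, residual norm and load-step history.
#' @export
solve_static <- function(mesh, material, holder = linear_elastic(1500, 0.3),
                         load = load_case(), n_increments = 20L, tol = 1e-6,
                         u0 = NULL) {
  stopifnot(inherits(mesh, "ap_mesh"), tol > 0)
  pb <- cornea_problem(mesh, material, holder, load)
  fe_solve(pb, n_increments = n_increments, tol = tol, u0 = u0)
}

#' Verify the consistency of the assembled tangent stiffness
#'
#' Compares the analytic global stiffness (including the follower-pressure
#' load stiffness) against a central finite difference of the global residual
#' at a given state, over the free degrees of freedom. Intended for small
#' meshes; cost grows linearly with the number of dofs.
#'
#' @inheritParams solve_static
#' @param u State at which to linearize (default: converged solution at the
#'   given load).
#' @param lambda Load factor at which to test (default 1).
#' @param h Finite-difference step.
#' @return Maximum absolute entry error of the stiffness, normalized by the
#'   largest stiffness entry (dimensionless).
#' @export
check_tangent <- function(mesh, material, holder = linear_elastic(1500, 0.3),
                          load = load_case(), u = NULL, lambda = 1,
                          h = 1e-6) {
  pb <- cornea_problem(mesh, material, holder, load)
  if (is.null(u)) u <- fe_solve(pb, n_increments = 5L)$u_flat
  fe_check_tangent(pb, u, lambda, h)
}

fe_check_tangent <- function(pb, u, lambda = 1, h = 1e-6) {
  free <- pb$free_dofs
  res <- fe_residual(pb, u, lambda, need_K = TRUE)
  K <- as.matrix(res$K[free, free, drop = FALSE])
  Kfd <- matrix(0, length(free), length(free))
  for (k in seq_along(free)) {
    up <- u; up[free[k]] <- up[free[k]] + h
    um <- u; um[free[k]] <- um[free[k]] - h
    Rp <- fe_residual(pb, up, lambda)$R[free]
    Rm <- fe_residual(pb, um, lambda)$R[free]
    Kfd[, k] <- (Rp - Rm) / (2 * h)
  }
  max(abs(Kfd - K)) / max(abs(K))
}

# Cauchy stress recovery at element centroids: returns nel x 4 matrix with
# columns (rr, zz, hoop, rz), full material response evaluated at the centroid.
recover_cauchy <- function(pb, u) {
  ur <- u[seq(1L, pb$ndof, by = 2L)]
  uz <- u[seq(2L, pb$ndof, by = 2L)]
  ure <- matrix(ur[pb$elem], pb$nel, 4L)
  uze <- matrix(uz[pb$elem], pb$nel, 4L)
  kin <- fe_kinematics(pb, 5L, ure, uze)
  gr <- mr_gradient_c(kin$cm, pb$c10, pb$c01, pb$kappa, part = "full")
  S11 <- 2 * gr[, 1L]; S22 <- 2 * gr[, 2L]; S33 <- 2 * gr[, 3L]; S12 <- gr[, 4L]
  J <- sqrt(kin$cm[, 3L] * (kin$cm[, 1L] * kin$cm[, 2L] - kin$cm[, 4L]^2))
  F11 <- kin$F11; F12 <- kin$F12; F21 <- kin$F21; F22 <- kin$F22
  # sigma = F S F' / J, in-plane block plus hoop
  s_rr <- (F11 * (S11 * F11 + S12 * F12) + F12 * (S12 * F11 + S22 * F12)) / J
  s_zz <- (F21 * (S11 * F21 + S12 * F22) + F22 * (S12 * F21 + S22 * F22)) / J
  s_rz <- (F11 * (S11 * F21 + S12 * F22) + F12 * (S12 * F21 + S22 * F22)) / J
  s_tt <- kin$lth^2 * S33 / J
  cbind(rr = s_rr, zz = s_zz, hoop = s_tt, rz = s_rz)
}

# Total current volume of a set of elements (2 pi r integral over deformed
# configuration) computed as integral of J over the reference domain.
fe_volume <- function(pb, u, which_elems = NULL) {
  ur <- u[seq(1L, pb$ndof, by = 2L)]
  uz <- u[seq(2L, pb$ndof, by = 2L)]
  ure <- matrix(ur[pb$elem], pb$nel, 4L)
  uze <- matrix(uz[pb$elem], pb$nel, 4L)
  sel <- if (is.null(which_elems)) rep(TRUE, pb$nel) else which_elems
  vol <- numeric(2L) # reference, current
  for (g in 1:4) {
    q <- pb$quad[[g]]
    kin <- fe_kinematics(pb, g, ure, uze)
    J <- sqrt(kin$cm[, 3L] * (kin$cm[, 1L] * kin$cm[, 2L] - kin$cm[, 4L]^2))
    w <- q$w0 / quad_wts[g] # unit-weight measure; 2x2 rule has weight 1 anyway
    vol[1L] <- vol[1L] + sum(w[sel])
    vol[2L] <- vol[2L] + sum((w * J)[sel])
  }
  list(reference = vol[1L], current = vol[2L])
}
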