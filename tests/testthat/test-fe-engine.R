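test_that("zero load yields the zero displacement field", {
  mesh <- tiny_mesh()
  sol <- solve_static(mesh, mooney_rivlin(0.05, 0.02), load = load_case(0))
  expect_true(sol$converged)
  expect_lt(max(abs(sol$u)), 1e-12)
})

test_that("inflated thin shell reproduces the Laplace membrane stress at the apex", {
  g <- cornea_geometry(posterior_radius = 8.6, thickness = 0.55)
  mesh <- build_mesh(g, 4, 60, 8)
  mat <- mooney_rivlin(0.3, 0.1)
  p <- 0.002
  pb <- airpuffr:::cornea_problem(mesh, mat, load = load_case(p))
  sol <- airpuffr:::fe_solve(pb, n_increments = 4)
  sig <- airpuffr:::recover_cauchy(pb, sol$u_flat)
  near_apex <- seq_len(4 * 3) # first three element columns
  s_mem <- mean(c(sig[near_apex, "rr"], sig[near_apex, "hoop"]))
  expect_equal(s_mem, p * (8.6 + 0.55 / 2) / (2 * 0.55), tolerance = 0.05)
})

test_that("assembled stiffness matches finite differences of the residual", {
  mesh <- tiny_mesh(nm = 20L, nh = 3L)
  mat <- mooney_rivlin(0.05, 0.02)
  # identity state without load: consistent to near machine precision
  err0 <- check_tangent(mesh, mat, load = load_case(0),
                        u = numeric(2 * nrow(mesh$nodes)))
  expect_lt(err0, 1e-6)
  # randomly perturbed state
  set.seed(31)
  u_rand <- stats::rnorm(2 * nrow(mesh$nodes), 0, 0.002)
  err1 <- check_tangent(mesh, mat, load = load_case(0), u = u_rand)
  expect_lt(err1, 1e-4)
  # converged state under follower pressure: load stiffness included
  err2 <- check_tangent(mesh, mat, load = load_case(mmhg_to_mpa(15)))
  expect_lt(err2, 1e-4)
})

test_that("solution is invariant under node reordering", {
  mesh <- tiny_mesh()
  mat <- mooney_rivlin(0.05, 0.02)
  lc <- load_case(mmhg_to_mpa(15))
  sol <- solve_static(mesh, mat, load = lc, n_increments = 4)

  set.seed(7)
  n <- nrow(mesh$nodes)
  perm <- sample.int(n) # new id of each old node
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes
  mesh2$nodes[perm, ] <- mesh$nodes
  mesh2$elem <- matrix(perm[mesh$elem], nrow(mesh$elem), 4L)
  mesh2$sets <- rapply(mesh$sets, function(s) {
    if (is.matrix(s)) matrix(perm[s], nrow(s), ncol(s)) else s
  }, classes = "ANY", how = "replace")
  for (nm in c("apex_anterior", "apex_posterior", "axis_nodes",
               "clamped_nodes", "anterior_nodes", "posterior_nodes")) {
    mesh2$sets[[nm]] <- perm[mesh$sets[[nm]]]
  }
  sol2 <- solve_static(mesh2, mat, load = lc, n_increments = 4)
  expect_lt(max(abs(sol2$u[perm, ] - sol$u)) / max(abs(sol$u)), 1e-8)
})

test_that("the quasi-static solution is path independent in the load stepping", {
  mesh <- tiny_mesh()
  mat <- mooney_rivlin(0.0375, 0.0125)
  lc <- load_case(mmhg_to_mpa(15))
  apex <- mesh$sets$apex_anterior
  u1 <- solve_static(mesh, mat, load = lc, n_increments = 3)$u[apex, 2]
  u2 <- solve_static(mesh, mat, load = lc, n_increments = 6)$u[apex, 2]
  expect_lt(abs(u1 - u2) / abs(u1), 0.001)
})

test_that("corneal material stays nearly incompressible at the peak load", {
  mesh <- tiny_mesh()
  mat <- phantom_material("S")
  puff <- function(r) 0.0045 * exp(-r^2 / (2 * 1.5^2))
  pb0 <- airpuffr:::cornea_problem(mesh, mat, load = load_case(mmhg_to_mpa(15)))
  s0 <- airpuffr:::fe_solve(pb0, n_increments = 4)
  pb <- airpuffr:::cornea_problem(mesh, mat,
                                  load = load_case(mmhg_to_mpa(15), puff),
                                  ramp_internal = FALSE)
  s1 <- airpuffr:::fe_solve(pb, n_increments = 5, u0 = s0$u_flat)
  vol <- airpuffr:::fe_volume(pb, s1$u_flat,
                              seq_len(nrow(mesh$elem)) %in% mesh$sets$cornea_elems)
  expect_lt(abs(vol$current - vol$reference) / vol$reference, 0.005)
})

test_that("near-incompressible bending matches thin-plate theory (no locking)", {
  pl <- plate_problem()
  sol <- airpuffr:::fe_solve(pl$pb, n_increments = 1)
  w_fe <- sol$u[pl$center_node, 2]
  mu <- 2 * (pl$mat$c10 + pl$mat$c01)
  kap <- pl$mat$bulk_penalty
  nu <- (3 * kap - 2 * mu) / (2 * (3 * kap + mu))
  E <- 2 * mu * (1 + nu)
  D <- E * pl$th^3 / (12 * (1 - nu^2))
  w_k <- pl$p * pl$a^4 / (64 * D)
  expect_equal(w_fe, w_k, tolerance = 0.05)
})

test_that("non-convergence raises a typed error carrying the load fraction", {
  mesh <- tiny_mesh()
  soft <- mooney_rivlin(0.002, 0.001)
  crush <- function(r) 0.5 * exp(-r^2 / 2) # far beyond any sustainable load
  err <- tryCatch(
    solve_static(mesh, soft, load = load_case(mmhg_to_mpa(15), crush),
                 n_increments = 2),
    ap_nonconvergence = function(e) e)
  expect_s3_class(err, "ap_nonconvergence")
  expect_true(err$last_lambda >= 0 && err$last_lambda < 1)
})
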