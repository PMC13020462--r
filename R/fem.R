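## Quasi-static conduction FEM on labeled tetrahedral meshes.
##
## First-order (P1) tetrahedral elements.  The governing equation is
## div(kappa grad V) = 0 with zero-flux natural conditions on the outer
## boundary and the airway walls, and terminal conditions on the electrode
## patches: every patch is condensed to a single equipotential unknown
## (complete electrode model with zero contact impedance); the source
## patch receives the total current I0, the sink patch is grounded, and
## any remaining patches float with zero net current.

#' Solver specification
#'
#' @param frequency Excitation frequency (Hz); default 10 kHz.
#' @param I0 Injected current amplitude (A); default 1 mA.
#' @param mode `"real"` (pure conduction, kappa = sigma) or `"complex"`
#'   (conduction + displacement current).
#' @param solver `"direct"` (sparse Cholesky) or `"iterative"`
#'   (Jacobi-preconditioned conjugate gradients).
#' @param rel_tolerance Relative residual tolerance of the iterative
#'   solver, in (0, 1e-2].
#' @return A `solve_spec` list.
#' @export
solve_spec <- function(frequency = 1e4, I0 = 1e-3,
                       mode = c("real", "complex"),
                       solver = c("direct", "iterative"),
                       rel_tolerance = 1e-8) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  if (I0 <= 0) stop("I0 must be positive")
  if (rel_tolerance <= 0 || rel_tolerance > 1e-2)
    stop("rel_tolerance must be in (0, 1e-2]")
  structure(list(frequency = frequency, I0 = I0, mode = mode,
                 solver = solver, rel_tolerance = rel_tolerance),
            class = "solve_spec")
}

## P1 shape-function gradients and volumes for all elements.
## Returns gx, gy, gz: m x 4 matrices (gradient of basis p in element e).
element_gradients <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  a <- nodes[elems[, 2], , drop = FALSE] - p1
  b <- nodes[elems[, 3], , drop = FALSE] - p1
  c_ <- nodes[elems[, 4], , drop = FALSE] - p1
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  ## rows of inv(M) for M = [a; b; c] (as rows): inv(M) = adj(M)/det,
  ## grad(lambda_{p+1}) = column p of inv... computed explicitly:
  ## inv(M)[i, j] = cof(M)[j, i] / det, grad lambda_2 = inv(M^T) e1 etc.
  ## Using M x = r with M rows a, b, c: lambda_(2,3,4) = M^{-T} ... direct:
  ## grad lambda_2 = (b x c)/det, grad lambda_3 = (c x a)/det,
  ## grad lambda_4 = (a x b)/det, grad lambda_1 = -(sum).
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- cross(b, c_) / det
  g3 <- cross(c_, a) / det
  g4 <- cross(a, b) / det
  g1 <- -(g2 + g3 + g4)
  list(gx = cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
       gy = cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
       gz = cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3]),
       vol = det / 6)
}

## Stiffness matrix for a per-element (real) coefficient vector.
assemble_matrix <- function(mesh, grads, coef) {
  m <- nrow(mesh$elems)
  pp <- rep(1:4, times = 4)
  qq <- rep(1:4, each = 4)
  w <- coef * grads$vol
  xs <- matrix(0, m, 16)
  for (t in 1:16) {
    p <- pp[t]; q <- qq[t]
    xs[, t] <- w * (grads$gx[, p] * grads$gx[, q] +
                      grads$gy[, p] * grads$gy[, q] +
                      grads$gz[, p] * grads$gz[, q])
  }
  Matrix::sparseMatrix(i = as.vector(mesh$elems[, pp]),
                       j = as.vector(mesh$elems[, qq]),
                       x = as.vector(xs),
                       dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
}

#' Assemble the conduction system on a labeled mesh
#'
#' Builds the P1 weak-form stiffness operator with per-element admittivity
#' `kappa(region, frequency, mode)` from the property table.  In complex
#' mode the real (conduction) and imaginary (displacement) parts are kept
#' as two real sparse matrices.
#'
#' @param mesh A `tet_mesh`.
#' @param table Tissue property table (default [tissue_table()]).
#' @param spec A [solve_spec()].
#' @return A `fem_system` with the operator, per-element admittivity and
#'   cached element gradients.
#' @export
assemble_system <- function(mesh, table = tissue_table(),
                            spec = solve_spec()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  tmap <- region_tissue_map()
  kappa_of <- function(labels) {
    out <- stats::setNames(rep(if (spec$mode == "complex") 0i else 0,
                               length(labels)), labels)
    for (rg in labels) {
      if (rg == "airway") next  # insulating lumen fraction
      tn <- tmap[[rg]]
      if (is.null(tn)) stop("no tissue mapped for region label '", rg, "'")
      props <- lookup_tissue(tn, spec$frequency, table)
      out[rg] <- admittivity(props, spec$mode)
    }
    out
  }
  if (!is.null(mesh$region_samples)) {
    ## partial-volume material averaging: mean admittivity over the
    ## interior sample points, so interface elements carry the mixed
    ## admittivity of the tissues they straddle
    klev <- kappa_of(mesh$region_levels)
    kappa <- (klev[mesh$region_samples[, 1]] +
                klev[mesh$region_samples[, 2]] +
                klev[mesh$region_samples[, 3]] +
                klev[mesh$region_samples[, 4]]) / 4
    kappa <- unname(kappa)
  } else {
    klev <- kappa_of(unique(mesh$region))
    kappa <- unname(klev[mesh$region])
  }
  grads <- element_gradients(mesh$nodes, mesh$elems)
  Kr <- assemble_matrix(mesh, grads, Re(kappa))
  Ki <- if (spec$mode == "complex") assemble_matrix(mesh, grads, Im(kappa))
        else NULL
  sys <- list(mesh = mesh, spec = spec, kappa = kappa, grads = grads,
              Kr = Kr, Ki = Ki, cache = new.env(parent = emptyenv()))
  class(sys) <- "fem_system"
  sys
}

## electrode patch names present in a mesh
mesh_patches <- function(mesh) {
  pn <- unique(mesh$face_patch)
  sort(pn[startsWith(pn, "electrode_")])
}

## Jacobi-preconditioned CG; returns list(x, rel_residual, iterations).
cg_solve <- function(A, b, tol, max_iter = 5000L) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b^2))
  it <- 0L
  while (sqrt(sum(r^2)) / nb > tol && it < max_iter) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    it <- it + 1L
  }
  list(x = x, rel_residual = sqrt(sum(r^2)) / nb, iterations = it)
}

#' Solve one tetrapolar injection
#'
#' Applies the terminal conditions (source patch: equipotential with total
#' current `I0`; sink patch: ground; other electrode patches: floating
#' equipotentials with zero net current) and solves the conduction system.
#'
#' The reduced system keeps every electrode patch as one condensed
#' unknown and instead eliminates a single interior reference node (a
#' gauge choice; the injection right-hand side sums to zero, so the
#' reduced solution is the exact discrete solution).  The potential is
#' re-grounded to the sink patch afterwards.  Because the reduced
#' operator does not depend on which patches drive, its factorisation is
#' computed once per system and reused across injections.
#'
#' @param system A `fem_system` from [assemble_system()].
#' @param source,sink Electrode labels (e.g. `"A"`, `"B"`), referring to
#'   boundary patches `electrode_<label>`.
#' @param spec Optional override of the solve spec stored in the system.
#' @param cg_max_iter Iteration cap of the iterative solver (mainly for
#'   constructing deliberately under-converged solves in tests).
#' @return A `field_solution` with nodal potential `V`, element current
#'   density `J`, patch potentials and weak patch fluxes.
#' @export
solve_injection <- function(system, source = "A", sink = "B", spec = NULL,
                            cg_max_iter = 5000L) {
  stopifnot(inherits(system, "fem_system"))
  if (is.null(spec)) spec <- system$spec
  mesh <- system$mesh
  patches <- mesh_patches(mesh)
  psrc <- paste0("electrode_", source)
  psnk <- paste0("electrode_", sink)
  for (p in c(psrc, psnk)) if (!(p %in% patches))
    stop("patch '", p, "' is empty or missing from the mesh")
  if (psrc == psnk) stop("source and sink patches must be disjoint")

  cache <- system$cache
  if (is.null(cache$red)) {
    n <- nrow(mesh$nodes)
    pnodes <- lapply(patches, function(p) patch_nodes(mesh, p))
    names(pnodes) <- patches
    map <- integer(n)
    in_patch <- rep(FALSE, n)
    for (p in patches) in_patch[pnodes[[p]]] <- TRUE
    free <- which(!in_patch)
    ref <- free[1]  # eliminated gauge node
    free <- free[-1]
    map[free] <- seq_along(free)
    nred <- length(free)
    patch_dof <- stats::setNames(integer(length(patches)), patches)
    for (p in patches) {
      nred <- nred + 1L
      patch_dof[p] <- nred
      map[pnodes[[p]]] <- nred
    }
    keep <- map > 0L
    T_ <- Matrix::sparseMatrix(i = which(keep), j = map[keep], x = 1,
                               dims = c(n, nred))
    reduce <- function(K)
      Matrix::forceSymmetric(Matrix::crossprod(T_, K %*% T_))
    cache$red <- list(T_ = T_, map = map, keep = keep, nred = nred,
                      patch_dof = patch_dof, pnodes = pnodes,
                      Kr_red = reduce(system$Kr),
                      Ki_red = if (!is.null(system$Ki)) reduce(system$Ki))
  }
  red <- cache$red
  Kr_red <- red$Kr_red
  n <- nrow(mesh$nodes)
  b <- numeric(red$nred)
  b[red$patch_dof[psrc]] <- spec$I0
  b[red$patch_dof[psnk]] <- -spec$I0

  get_chol <- function() {
    if (is.null(cache$chol))
      cache$chol <- Matrix::Cholesky(Kr_red, LDL = FALSE, perm = TRUE)
    cache$chol
  }

  residual <- NA_real_
  iters <- 0L
  if (spec$mode == "real") {
    if (spec$solver == "direct") {
      u <- as.numeric(Matrix::solve(get_chol(), b))
      residual <- sqrt(sum((as.numeric(Kr_red %*% u) - b)^2)) / sqrt(sum(b^2))
    } else {
      out <- cg_solve(Kr_red, b, tol = spec$rel_tolerance,
                      max_iter = cg_max_iter)
      u <- out$x
      residual <- out$rel_residual
      iters <- out$iterations
      if (residual > spec$rel_tolerance)
        warning("iterative solver stopped at relative residual ",
                signif(residual, 3), " > tolerance ", spec$rel_tolerance)
    }
  } else {
    Ki_red <- red$Ki_red
    ch <- get_chol()
    u <- as.complex(as.numeric(Matrix::solve(ch, b)))
    nb <- sqrt(sum(Mod(b)^2))
    for (it in seq_len(200L)) {
      r <- b - (as.numeric(Kr_red %*% Re(u)) - as.numeric(Ki_red %*% Im(u))) -
        1i * (as.numeric(Kr_red %*% Im(u)) + as.numeric(Ki_red %*% Re(u)))
      residual <- sqrt(sum(Mod(r)^2)) / nb
      iters <- it
      if (residual < 1e-10) break
      u <- u + as.numeric(Matrix::solve(ch, Re(r))) +
        1i * as.numeric(Matrix::solve(ch, Im(r)))
    }
    if (residual > 1e-8)
      warning("complex fixed-point solve stopped at relative residual ",
              signif(residual, 3))
  }

  ## expand to nodal potentials and re-ground to the sink patch
  shift <- u[red$patch_dof[psnk]]
  u <- u - shift
  V <- if (spec$mode == "complex") complex(real = rep(0, n)) else numeric(n)
  V[red$keep] <- u[red$map[red$keep]]
  V[!red$keep] <- -shift  # the gauge node

  ## element current density J = -kappa grad V
  Vm <- matrix(V[mesh$elems], ncol = 4)
  gr <- system$grads
  dVx <- rowSums(gr$gx * Vm); dVy <- rowSums(gr$gy * Vm)
  dVz <- rowSums(gr$gz * Vm)
  J <- cbind(-system$kappa * dVx, -system$kappa * dVy, -system$kappa * dVz)

  ## weak boundary fluxes per patch (exact discrete fluxes)
  rfull <- as.numeric(system$Kr %*% Re(V))
  if (spec$mode == "complex")
    rfull <- (rfull - as.numeric(system$Ki %*% Im(V))) +
      1i * (as.numeric(system$Kr %*% Im(V)) + as.numeric(system$Ki %*% Re(V)))
  patch_flux <- vapply(patches, function(p) sum(rfull[red$pnodes[[p]]]),
                       rfull[1] * 0)
  other <- setdiff(unique(as.vector(mesh$faces)),
                   unlist(red$pnodes, use.names = FALSE))
  other_flux <- sum(rfull[other])

  patch_V <- vapply(patches, function(p) u[red$patch_dof[p]], V[1])

  sol <- list(V = V, J = J, patch_V = patch_V, patch_flux = patch_flux,
              other_boundary_flux = other_flux,
              injection = c(source = source, sink = sink),
              spec = spec, residual = residual, iterations = iters,
              system = system)
  class(sol) <- "field_solution"
  sol
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("Field solution: injection %s -> %s, f = %g Hz, mode = %s\n",
              x$injection["source"], x$injection["sink"],
              x$spec$frequency, x$spec$mode))
  cat(sprintf("  relative residual %.2e; patch potentials (V):\n", x$residual))
  print(signif(x$patch_V, 5))
  invisible(x)
}

#' Current conservation report
#'
#' Weak (discretely exact) boundary fluxes per electrode patch, the total
#' flux through the non-electrode boundary, and pass/fail flags at 0.5 %
#' of the injected current.
#'
#' @param sol A `field_solution`.
#' @return A list with a per-patch data frame `patches`, the
#'   `other_boundary_flux`, the overall `total`, and `pass`.
#' @export
check_current_conservation <- function(sol) {
  stopifnot(inherits(sol, "field_solution"))
  I0 <- sol$spec$I0
  src <- paste0("electrode_", sol$injection["source"])
  snk <- paste0("electrode_", sol$injection["sink"])
  expect <- stats::setNames(rep(0, length(sol$patch_flux)),
                            names(sol$patch_flux))
  expect[src] <- I0
  expect[snk] <- -I0
  dev <- Mod(sol$patch_flux - expect)
  df <- data.frame(patch = names(sol$patch_flux),
                   flux = as.numeric(Mod(sol$patch_flux)),
                   expected = as.numeric(abs(expect)),
                   deviation_frac_I0 = as.numeric(dev) / I0,
                   pass = as.numeric(dev) / I0 <= 0.005)
  rownames(df) <- NULL
  total <- Mod(sum(sol$patch_flux) + sol$other_boundary_flux)
  list(patches = df,
       other_boundary_flux = Mod(sol$other_boundary_flux),
       total = total,
       pass = all(df$pass) && Mod(sol$other_boundary_flux) / I0 <= 0.005 &&
         total / I0 <= 0.005)
}
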