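## Steady incompressible laminar flow on a staggered (MAC) grid with
## blocked solid cells. The Stokes saddle-point system is solved exactly:
## Cholesky-factored momentum Laplacians + conjugate-gradient on the
## pressure Schur complement (Uzawa), preconditioned by the scaled
## pressure mass matrix. The convective (inertial) term is available via
## Picard defect-correction for full laminar Navier-Stokes.

#' Fluid properties
#' @param density kg/m^3 (> 0); default water-like 1000.
#' @param viscosity dynamic viscosity, Pa s (> 0); default 1e-3.
#' @export
fluidProps <- function(density = 1000, viscosity = 1e-3) {
  if (density <= 0 || viscosity <= 0)
    stop("fluidProps: density and viscosity must be positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity),
            class = "exo_fluid_props")
}

#' Flow boundary conditions
#'
#' Uniform inlet velocity on the left boundary, flux-matched uniform
#' outflow on the right boundary with a reference pressure, and slip
#' (symmetry) or no-slip lateral walls. Solid surfaces are always
#' no-slip. Pressure is reported relative to the outlet reference.
#'
#' @param inlet_velocity inlet x-velocity (m/s, >= 0), uniform over the
#'   open part of the left boundary.
#' @param outlet_pressure reference pressure at the outlet (Pa).
#' @param lateral \code{"slip"} (symmetry, default) or \code{"noslip"}
#'   for the bottom/top walls.
#' @export
flowBCs <- function(inlet_velocity, outlet_pressure = 0,
                    lateral = c("slip", "noslip")) {
  lateral <- match.arg(lateral)
  if (inlet_velocity < 0)
    stop("flowBCs: inlet velocity must be >= 0", call. = FALSE)
  structure(list(inlet_velocity = inlet_velocity,
                 outlet_pressure = outlet_pressure, lateral = lateral),
            class = "exo_flow_bcs")
}

#' Reynolds number
#'
#' rho U L / mu for a characteristic speed and length; interstitial flow
#' sits at Re ~ 1e-5 - 1e-3, deep in the Stokes regime.
#'
#' @param props an \code{exo_fluid_props}.
#' @param U characteristic speed (m/s).
#' @param L characteristic length (m).
#' @export
reynoldsNumber <- function(props, U, L) {
  stopifnot(U >= 0, L > 0)
  props$density * U * L / props$viscosity
}

## internal: solid test for cell (i,j) with out-of-range = not solid
isSolid <- function(solid, i, j) {
  nx <- nrow(solid); ny <- ncol(solid)
  ok <- i >= 1 & i <= nx & j >= 1 & j <= ny
  r <- logical(length(i)); r[ok] <- solid[cbind(i[ok], j[ok])]
  r
}

#' Solve steady incompressible flow on a masked grid
#'
#' Left-boundary uniform inlet, right-boundary flux-matched outflow,
#' no-slip on solid surfaces. By default the Stokes equations are solved
#' (exact for the vanishing Reynolds numbers of interstitial flow); with
#' \code{inertia = TRUE} the convective term is added by Picard
#' defect-correction iterations.
#'
#' @param grid Cartesian \code{exo_grid}.
#' @param mask \code{exo_mask}; there must be a connected FLUID path from
#'   the left to the right boundary.
#' @param props an \code{exo_fluid_props}.
#' @param bcs an \code{exo_flow_bcs}.
#' @param tol relative tolerance on the pressure-CG residual
#'   (continuity defect), default 1e-12.
#' @param inertia include the convective term (Picard iterations)?
#' @param maxit_picard,maxit_cg iteration caps.
#' @return object of class \code{exo_flow}: face-normal velocities
#'   \code{uf} ((nx+1) x ny), \code{vf} (nx x (ny+1)), cell pressure
#'   \code{p} (nx x ny, NA in solids), \code{div} (max abs cell
#'   divergence, 1/s), \code{div_rel} (normalized by inlet flux / cell
#'   volume), mass fluxes, iteration counts.
#' @export
solveFlow <- function(grid, mask, props = fluidProps(), bcs,
                      tol = 1e-12, inertia = FALSE,
                      maxit_picard = 25L, maxit_cg = 2000L) {
  stopifnot(grid$coord == "cartesian")
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx; dy <- grid$dy
  mu <- props$viscosity
  solid <- mask$solid; fluid <- !solid

  # connectivity: flood fill from open inlet cells
  open_in <- which(fluid[1, ]); open_out <- which(fluid[nx, ])
  if (!length(open_in) || !length(open_out))
    stop("solveFlow: inlet or outlet boundary entirely blocked", call. = FALSE)
  reach <- matrix(FALSE, nx, ny)
  frontier <- cbind(1L, open_in); reach[frontier] <- TRUE
  while (nrow(frontier)) {
    nbr <- rbind(cbind(frontier[, 1] + 1L, frontier[, 2]),
                 cbind(frontier[, 1] - 1L, frontier[, 2]),
                 cbind(frontier[, 1], frontier[, 2] + 1L),
                 cbind(frontier[, 1], frontier[, 2] - 1L))
    ok <- nbr[, 1] >= 1 & nbr[, 1] <= nx & nbr[, 2] >= 1 & nbr[, 2] <= ny
    nbr <- nbr[ok, , drop = FALSE]
    ok <- fluid[nbr] & !reach[nbr]
    nbr <- unique(nbr[ok, , drop = FALSE])
    reach[nbr] <- TRUE
    frontier <- nbr
  }
  if (!any(reach[nx, ]))
    stop("solveFlow: no connected FLUID path from inlet to outlet",
         call. = FALSE)

  # Dirichlet values on boundary/solid faces
  Uin <- bcs$inlet_velocity
  Qin <- Uin * dy * grid$depth * length(open_in)
  uout <- if (length(open_out)) Qin / (dy * grid$depth * length(open_out)) else 0

  # classify u-faces: fi = 1..nx+1 (face fi west of cell fi); unknown iff
  # interior and both adjacent cells fluid
  u_known <- matrix(0, nx + 1, ny)
  u_is_known <- matrix(TRUE, nx + 1, ny)
  u_is_known[2:nx, ] <- !(fluid[-nx, , drop = FALSE] & fluid[-1, , drop = FALSE])
  u_known[1, open_in] <- Uin
  u_known[nx + 1, open_out] <- uout
  v_known <- matrix(0, nx, ny + 1)
  v_is_known <- matrix(TRUE, nx, ny + 1)
  v_is_known[, 2:ny] <- !(fluid[, -ny, drop = FALSE] & fluid[, -1, drop = FALSE])

  uidx <- matrix(0L, nx + 1, ny); widx <- which(!u_is_known)
  uidx[widx] <- seq_along(widx); nu <- length(widx)
  vidx <- matrix(0L, nx, ny + 1); wv <- which(!v_is_known)
  vidx[wv] <- seq_along(wv); nv <- length(wv)
  pidx <- matrix(0L, nx, ny); wp <- which(fluid)
  pidx[wp] <- seq_along(wp); np <- length(wp)
  if (nu == 0 && nv == 0) {
    # fully blocked interior (or 1-cell-wide everything known)
    stop("solveFlow: no interior velocity unknowns; grid too coarse",
         call. = FALSE)
  }

  lat_noslip <- bcs$lateral == "noslip"

  ## ---- momentum operator for u -------------------------------------------
  iu <- which(!u_is_known, arr.ind = TRUE)
  fi <- iu[, 1]; j <- iu[, 2]; me <- uidx[iu]
  ti <- tj <- tv <- integer(0); tx <- numeric(0)
  bu <- numeric(nu)
  addu <- function(rows, cols, vals) {
    ti <<- c(ti, rows); tj <<- c(tj, cols); tx <<- c(tx, vals)
  }
  diagu <- rep(2 * mu / dx^2, nu)   # from the two x-neighbors
  # x-neighbors (always exist: fi-1 >= 1, fi+1 <= nx+1)
  for (s in c(-1L, 1L)) {
    nfi <- fi + s
    nbr_unknown <- !u_is_known[cbind(nfi, j)]
    w <- which(nbr_unknown)
    if (length(w)) addu(me[w], uidx[cbind(nfi[w], j[w])], rep(-mu / dx^2, length(w)))
    w <- which(!nbr_unknown)
    if (length(w)) bu[me[w]] <- bu[me[w]] + (mu / dx^2) * u_known[cbind(nfi[w], j[w])]
  }
  # y-neighbors: may be wall (ghost) or solid-adjacent (mirror no-slip)
  for (s in c(-1L, 1L)) {
    nj <- j + s
    atwall <- nj < 1 | nj > ny
    w <- which(atwall)
    if (length(w)) {
      if (lat_noslip) diagu[me[w]] <- diagu[me[w]] + 2 * mu / dy^2
      # slip: ghost = self -> zero contribution
    }
    w <- which(!atwall)
    if (length(w)) {
      nfi <- fi[w]; njj <- nj[w]
      # neighbor u-face is next to solid if either adjacent cell solid
      nsolid <- isSolid(solid, nfi - 1L, njj) | isSolid(solid, nfi, njj)
      wk <- w[!nsolid & !u_is_known[cbind(nfi, njj)]]
      if (length(wk)) {
        diagu[me[wk]] <- diagu[me[wk]] + mu / dy^2
        addu(me[wk], uidx[cbind(fi[wk] + 0L, j[wk] + s)], rep(-mu / dy^2, length(wk)))
      }
      # neighbor known-zero because solid-adjacent: mirror no-slip about
      # the intervening cell boundary (ghost = -self)
      ws <- w[nsolid]
      if (length(ws)) diagu[me[ws]] <- diagu[me[ws]] + 2 * mu / dy^2
      # neighbor is a known boundary u (shouldn't happen for interior rows)
      wb <- w[!nsolid & u_is_known[cbind(nfi, njj)]]
      if (length(wb)) {
        diagu[me[wb]] <- diagu[me[wb]] + mu / dy^2
        bu[me[wb]] <- bu[me[wb]] + (mu / dy^2) * u_known[cbind(fi[wb], j[wb] + s)]
      }
    }
  }
  Au <- Matrix::sparseMatrix(i = c(seq_len(nu), ti), j = c(seq_len(nu), tj),
                             x = c(diagu, tx), dims = c(nu, nv * 0 + nu))
  # pressure gradient for u: (p_E - p_W)/dx, both cells fluid by construction
  Gu <- Matrix::sparseMatrix(
    i = c(me, me),
    j = c(pidx[cbind(fi, j)], pidx[cbind(fi - 1L, j)]),
    x = c(rep(1 / dx, nu), rep(-1 / dx, nu)), dims = c(nu, np))

  ## ---- momentum operator for v -------------------------------------------
  iv <- which(!v_is_known, arr.ind = TRUE)
  vi <- iv[, 1]; fj <- iv[, 2]; mev <- vidx[iv]
  ti <- tj <- integer(0); tx <- numeric(0)
  bv <- numeric(nv)
  diagv <- rep(2 * mu / dy^2, nv)
  for (s in c(-1L, 1L)) {
    nfj <- fj + s
    nbr_unknown <- !v_is_known[cbind(vi, nfj)]
    w <- which(nbr_unknown)
    if (length(w)) {
      ti <- c(ti, mev[w]); tj <- c(tj, vidx[cbind(vi[w], nfj[w])])
      tx <- c(tx, rep(-mu / dy^2, length(w)))
    }
    w <- which(!nbr_unknown)
    if (length(w)) bv[mev[w]] <- bv[mev[w]] + (mu / dy^2) * v_known[cbind(vi[w], nfj[w])]
  }
  for (s in c(-1L, 1L)) {
    ni <- vi + s
    atwall <- ni < 1 | ni > nx
    w <- which(atwall)
    if (length(w)) {
      # left/right boundaries: inlet/outlet planes; tangential v there is
      # 0 for a uniform normal-velocity profile -> mirror (ghost = -self)
      diagv[mev[w]] <- diagv[mev[w]] + 2 * mu / dx^2
    }
    w <- which(!atwall)
    if (length(w)) {
      nii <- ni[w]; nfj <- fj[w]
      nsolid <- isSolid(solid, nii, nfj - 1L) | isSolid(solid, nii, nfj)
      wk <- w[!nsolid & !v_is_known[cbind(nii, nfj)]]
      if (length(wk)) {
        diagv[mev[wk]] <- diagv[mev[wk]] + mu / dx^2
        ti <- c(ti, mev[wk]); tj <- c(tj, vidx[cbind(vi[wk] + s, fj[wk])])
        tx <- c(tx, rep(-mu / dx^2, length(wk)))
      }
      ws <- w[nsolid]
      if (length(ws)) diagv[mev[ws]] <- diagv[mev[ws]] + 2 * mu / dx^2
      wb <- w[!nsolid & v_is_known[cbind(nii, nfj)]]
      if (length(wb)) {
        diagv[mev[wb]] <- diagv[mev[wb]] + mu / dx^2
        bv[mev[wb]] <- bv[mev[wb]] + (mu / dx^2) * v_known[cbind(vi[wb] + s, fj[wb])]
      }
    }
  }
  Av <- Matrix::sparseMatrix(i = c(seq_len(nv), ti), j = c(seq_len(nv), tj),
                             x = c(diagv, tx), dims = c(nv, nv))
  Gv <- Matrix::sparseMatrix(
    i = c(mev, mev),
    j = c(pidx[cbind(vi, fj)], pidx[cbind(vi, fj - 1L)]),
    x = c(rep(1 / dy, nv), rep(-1 / dy, nv)), dims = c(nv, np))

  ## ---- continuity: B_u u + B_v v = gdiv (known fluxes to RHS) ------------
  # div_cell = (uE - uW)/dx + (vN - vS)/dy = 0
  ip <- which(fluid, arr.ind = TRUE)
  ci <- ip[, 1]; cj <- ip[, 2]; mep <- pidx[ip]
  bi <- bj <- integer(0); bx <- numeric(0)
  gdiv <- numeric(np)
  addc <- function(face_unknown, fidx_v, sgn, h, kval) {
    w <- which(face_unknown)
    if (length(w)) {
      bi <<- c(bi, mep[w]); bj <<- c(bj, fidx_v[w]); bx <<- c(bx, rep(sgn / h, length(w)))
    }
    w <- which(!face_unknown)
    if (length(w)) gdiv[mep[w]] <<- gdiv[mep[w]] - sgn * kval[w] / h
  }
  # east u-face (fi = ci+1), west (fi = ci)
  fiE <- cbind(ci + 1L, cj); fiW <- cbind(ci, cj)
  addc(!u_is_known[fiE], uidx[fiE], +1, dx, u_known[fiE])
  addc(!u_is_known[fiW], uidx[fiW], -1, dx, u_known[fiW])
  Bu <- Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(np, nu))
  bi <- bj <- integer(0); bx <- numeric(0)
  fjN <- cbind(ci, cj + 1L); fjS <- cbind(ci, cj)
  addc(!v_is_known[fjN], vidx[fjN], +1, dy, v_known[fjN])
  addc(!v_is_known[fjS], vidx[fjS], -1, dy, v_known[fjS])
  Bv <- Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(np, nv))

  ## ---- Schur-complement CG on pressure -----------------------------------
  Fu <- Matrix::Cholesky(Matrix::forceSymmetric(Au), LDL = FALSE)
  Fv <- if (nv > 0) Matrix::Cholesky(Matrix::forceSymmetric(Av), LDL = FALSE) else NULL
  solveA <- function(b_u, b_v) {
    list(u = as.numeric(Matrix::solve(Fu, b_u)),
         v = if (nv > 0) as.numeric(Matrix::solve(Fv, b_v)) else numeric(0))
  }
  applyS <- function(p) {
    s <- solveA(as.numeric(Gu %*% p), if (nv > 0) as.numeric(Gv %*% p) else numeric(0))
    as.numeric(Bu %*% s$u) + (if (nv > 0) as.numeric(Bv %*% s$v) else 0)
  }
  proj <- function(x) x - mean(x)          # remove constant-pressure nullspace
  picard <- 0L; cg_total <- 0L
  conv_u <- numeric(nu); conv_v <- numeric(nv)   # convective defect
  repeat {
    rhs_mom_u <- bu - conv_u
    rhs_mom_v <- bv - conv_v
    s0 <- solveA(rhs_mom_u, rhs_mom_v)
    # S p = B A^-1 b - g   (S = -B A^-1 G is SPD up to sign; see below)
    rhs_p <- proj(as.numeric(Bu %*% s0$u) +
                    (if (nv > 0) as.numeric(Bv %*% s0$v) else 0) - gdiv)
    # B = -G^T (up to the 1/h scalings, exactly, by construction), so
    # -S = G^T A^-1 G is SPD on the mean-zero subspace; CG on  (-S) p = -rhs_p
    p <- numeric(np)
    r <- proj(-rhs_p)
    rhs_norm <- sqrt(sum(r^2))
    if (rhs_norm > 0) {
      Minv <- dx * dy / mu                  # mass preconditioner (uniform)
      z <- Minv * r; d <- z
      rz <- sum(r * z)
      for (it in seq_len(maxit_cg)) {
        Sd <- proj(-applyS(d))
        alpha <- rz / sum(d * Sd)
        p <- p + alpha * d
        r <- r - alpha * Sd
        if (sqrt(sum(r^2)) <= tol * rhs_norm) break
        z <- Minv * r
        rz_new <- sum(r * z)
        d <- z + (rz_new / rz) * d
        rz <- rz_new
      }
      cg_total <- cg_total + it
      if (sqrt(sum(r^2)) > tol * rhs_norm)
        stop(sprintf("solveFlow: pressure CG did not converge (residual %.3g after %d iterations)",
                     sqrt(sum(r^2)) / rhs_norm, maxit_cg), call. = FALSE)
      p <- proj(p)
    }
    sol <- solveA(rhs_mom_u - as.numeric(Gu %*% p),
                  if (nv > 0) rhs_mom_v - as.numeric(Gv %*% p) else numeric(0))
    uvec <- sol$u; vvec <- sol$v
    picard <- picard + 1L
    if (!inertia || picard >= maxit_picard) break
    # Picard defect-correction: explicit convective term rho (u . grad) u
    uf <- u_known; uf[!u_is_known] <- uvec
    vf <- v_known; vf[!v_is_known] <- vvec
    cv <- convectiveTerm(uf, vf, props$density, dx, dy)
    new_u <- cv$cu[!u_is_known]; new_v <- cv$cv[!v_is_known]
    delta <- max(abs(new_u - conv_u), if (nv) abs(new_v - conv_v) else 0)
    conv_u <- new_u; conv_v <- new_v
    scale_ref <- mu * max(abs(uvec), 1e-300) / dx^2
    if (delta <= 1e-10 * scale_ref + 1e-300) break
  }

  uf <- u_known; uf[!u_is_known] <- uvec
  vf <- v_known; vf[!v_is_known] <- vvec
  # divergence check over fluid cells
  divm <- (uf[2:(nx + 1), , drop = FALSE] - uf[1:nx, , drop = FALSE]) / dx +
          (vf[, 2:(ny + 1), drop = FALSE] - vf[, 1:ny, drop = FALSE]) / dy
  divm[solid] <- 0
  div_max <- max(abs(divm))
  div_rel <- if (Qin > 0) div_max * dx * dy * grid$depth / Qin else div_max
  pm <- matrix(NA_real_, nx, ny)
  pm[fluid] <- p
  # shift so the outlet-column mean equals the reference pressure
  pm <- pm - mean(pm[nx, open_out]) + bcs$outlet_pressure
  influx <- sum(uf[1, ]) * dy * grid$depth
  outflux <- sum(uf[nx + 1, ]) * dy * grid$depth
  structure(list(uf = uf, vf = vf, p = pm,
                 div = div_max, div_rel = div_rel,
                 influx = influx, outflux = outflux,
                 picard_iterations = picard, cg_iterations = cg_total,
                 props = props, bcs = bcs),
            class = "exo_flow")
}

## internal: convective term rho d(ui uj)/dxj at u- and v-face locations,
## first-order upwind; used only for the optional inertial correction
convectiveTerm <- function(uf, vf, rho, dx, dy) {
  nx <- nrow(vf); ny <- ncol(uf)
  cu <- matrix(0, nx + 1, ny)
  cv <- matrix(0, nx, ny + 1)
  # u at faces fi = 2..nx: upwind gradients from neighbors
  for (fi in 2:nx) for (j in 1:ny) {
    u <- uf[fi, j]
    v <- 0.25 * (vf[fi - 1, j] + vf[fi - 1, j + 1] + vf[fi, j] + vf[fi, j + 1])
    dudx <- if (u >= 0) (u - uf[fi - 1, j]) / dx else (uf[fi + 1, j] - u) / dx
    dudy <- if (v >= 0) {
      if (j > 1) (u - uf[fi, j - 1]) / dy else 0
    } else {
      if (j < ny) (uf[fi, j + 1] - u) / dy else 0
    }
    cu[fi, j] <- rho * (u * dudx + v * dudy)
  }
  if (ny >= 2) for (i in 1:nx) for (fj in 2:ny) {
    v <- vf[i, fj]
    u <- 0.25 * (uf[i, fj - 1] + uf[i + 1, fj - 1] + uf[i, fj] + uf[i + 1, fj])
    dvdy <- if (v >= 0) (v - vf[i, fj - 1]) / dy else (vf[i, fj + 1] - v) / dy
    dvdx <- if (u >= 0) {
      if (i > 1) (v - vf[i - 1, fj]) / dx else 0
    } else {
      if (i < nx) (vf[i + 1, fj] - v) / dx else 0
    }
    cv[i, fj] <- rho * (u * dvdx + v * dvdy)
  }
  list(cu = cu, cv = cv)
}

#' @export
print.exo_flow <- function(x, ...) {
  cat(sprintf("<exo_flow> max|u| = %.4g m/s, max|div| = %.3g 1/s (rel %.3g)\n",
              max(abs(x$uf), abs(x$vf)), x$div, x$div_rel))
  cat(sprintf("  influx %.6g, outflux %.6g m^3/s; CG iterations %d\n",
              x$influx, x$outflux, x$cg_iterations))
  invisible(x)
}

#' Trace streamlines through a velocity field
#'
#' Fourth-order Runge-Kutta integration of seed points through the
#' bilinearly interpolated face-velocity field; tracing stops at domain
#' boundaries, SOLID cells, stagnation, or the length cap.
#'
#' @param grid an \code{exo_grid}.
#' @param flow an \code{exo_flow} (or list with \code{uf}, \code{vf}).
#' @param mask an \code{exo_mask}.
#' @param seed_points n x 2 matrix of starting coordinates (m).
#' @param step integration step (m); default half the cell size.
#' @param max_len maximum arc length (m); default 10 domain widths.
#' @return list of polyline matrices (two columns x, y); seeds inside
#'   SOLID cells are skipped with a warning.
#' @export
computeStreamlines <- function(grid, flow, mask, seed_points,
                               step = NULL, max_len = NULL) {
  if (is.null(step)) step <- 0.5 * min(grid$dx, grid$dy)
  Lx <- grid$xf[grid$nx + 1] - grid$xf[1]
  if (is.null(max_len)) max_len <- 10 * Lx
  interp <- function(pt) {
    x <- pt[1]; y <- pt[2]
    # u at (xf, yc); v at (xc, yf)
    u <- bilinear(grid$xf, grid$yc, flow$uf, x, y)
    v <- bilinear(grid$xc, grid$yf, flow$vf, x, y)
    c(u, v)
  }
  inDomain <- function(pt) {
    pt[1] >= grid$xf[1] && pt[1] <= grid$xf[grid$nx + 1] &&
      pt[2] >= grid$yf[1] && pt[2] <= grid$yf[grid$ny + 1]
  }
  inSolid <- function(pt) {
    i <- min(max(1L, 1L + floor((pt[1] - grid$xf[1]) / grid$dx)), grid$nx)
    j <- min(max(1L, 1L + floor((pt[2] - grid$yf[1]) / grid$dy)), grid$ny)
    mask$solid[i, j]
  }
  vmax <- max(abs(flow$uf), abs(flow$vf))
  out <- list()
  for (s in seq_len(nrow(seed_points))) {
    pt <- as.numeric(seed_points[s, ])
    if (!inDomain(pt) || inSolid(pt)) {
      warning("computeStreamlines: seed ", s, " inside SOLID or outside domain; skipped")
      next
    }
    pts <- matrix(pt, 1, 2)
    len <- 0
    while (len < max_len) {
      vel1 <- interp(pt); sp1 <- sqrt(sum(vel1^2))
      if (sp1 < 1e-12 * vmax) break
      h <- step / sp1                      # parameter step ~ arclength
      k1 <- vel1
      k2 <- interp(pt + 0.5 * h * k1)
      k3 <- interp(pt + 0.5 * h * k2)
      k4 <- interp(pt + h * k3)
      newpt <- pt + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!inDomain(newpt) || inSolid(newpt)) break
      len <- len + sqrt(sum((newpt - pt)^2))
      pt <- newpt
      pts <- rbind(pts, pt)
      if (nrow(pts) > 100000) break
    }
    out[[length(out) + 1L]] <- pts
  }
  out
}

#' Interpolate the face-velocity field at a point
#'
#' Bilinear interpolation of the staggered velocities (u at x-faces, v at
#' y-faces) to an arbitrary location; the interpolation used by
#' [computeStreamlines()].
#'
#' @param grid an \code{exo_grid}.
#' @param flow an \code{exo_flow} (or list with \code{uf}, \code{vf}).
#' @param x,y coordinates (m), scalars.
#' @return numeric \code{c(u, v)} in m/s.
#' @export
interpVelocity <- function(grid, flow, x, y) {
  c(bilinear(grid$xf, grid$yc, flow$uf, x, y),
    bilinear(grid$xc, grid$yf, flow$vf, x, y))
}

## internal: bilinear interpolation on a tensor grid with constant
## extrapolation at the edges
bilinear <- function(xs, ys, F, x, y) {
  nxp <- length(xs); nyp <- length(ys)
  i <- findInterval(x, xs); i <- min(max(i, 1L), nxp - 1L)
  j <- findInterval(y, ys); j <- min(max(j, 1L), nyp - 1L)
  tx <- (x - xs[i]) / (xs[i + 1] - xs[i]); tx <- min(max(tx, 0), 1)
  ty <- (y - ys[j]) / (ys[j + 1] - ys[j]); ty <- min(max(ty, 0), 1)
  (1 - tx) * (1 - ty) * F[i, j] + tx * (1 - ty) * F[i + 1, j] +
    (1 - tx) * ty * F[i, j + 1] + tx * ty * F[i + 1, j + 1]
}
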