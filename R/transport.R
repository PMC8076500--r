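## Finite-volume scalar transport: explicit advective fluxes with
## selectable face reconstruction + implicit (backward-Euler) or explicit
## diffusion, on Cartesian or axisymmetric grids with blocked solid cells.

#' Transport parameters
#'
#' @param gamma diffusion coefficient(s), m^2/s; one value per species.
#' @param scheme advective face-reconstruction scheme: \code{"upwind1"}
#'   (first-order upwind), \code{"upwind2"} (second-order linear upwind),
#'   \code{"quick"} (quadratic upstream interpolation, weights 3/8
#'   downstream + 6/8 upstream - 1/8 far upstream) or \code{"muscl"}
#'   (limited linear reconstruction).
#' @param diffusion \code{"implicit"} (unconditionally stable,
#'   default) or \code{"explicit"}.
#' @param limiter slope limiter for MUSCL: \code{"minmod"} (default) or
#'   \code{"vanleer"}.
#' @param integrator time integration: \code{"euler"} (first order:
#'   forward-Euler advection + backward-Euler diffusion; robust default
#'   for long scenario runs) or \code{"heun"} (second order: Strang
#'   splitting with Crank-Nicolson diffusion half-steps around a Heun
#'   advection step; used by the verification benchmark so the spatial
#'   order of the face schemes is observable).
#' @return object of class \code{exo_transport_params}.
#' @export
transportParams <- function(gamma, scheme = c("muscl", "upwind1", "upwind2",
                                              "quick"),
                            diffusion = c("implicit", "explicit"),
                            limiter = c("minmod", "vanleer"),
                            integrator = c("euler", "heun")) {
  scheme <- match.arg(scheme)
  diffusion <- match.arg(diffusion)
  limiter <- match.arg(limiter)
  integrator <- match.arg(integrator)
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop("transportParams: gamma must be positive and finite", call. = FALSE)
  structure(list(gamma = gamma, n_species = length(gamma), scheme = scheme,
                 diffusion = diffusion, limiter = limiter,
                 integrator = integrator),
            class = "exo_transport_params")
}

#' Transport boundary conditions
#'
#' One record per outer side. \code{"wall"}: zero advective and diffusive
#' flux. \code{"dirichlet"}: prescribed boundary concentration (scalar or
#' \code{function(x, y, t)}), applied to both advective inflow values and
#' diffusive fluxes. \code{"outflow"}: zero-gradient.
#'
#' @param type one of \code{"wall"}, \code{"dirichlet"}, \code{"outflow"}.
#' @param value scalar or function(x, y, t) for dirichlet sides.
#' @export
bcSide <- function(type = c("wall", "dirichlet", "outflow"), value = 0) {
  type <- match.arg(type)
  list(type = type, value = value)
}

#' @rdname bcSide
#' @param left,right,bottom,top per-side records from [bcSide()].
#' @export
transportBC <- function(left = bcSide("wall"), right = bcSide("wall"),
                        bottom = bcSide("wall"), top = bcSide("wall")) {
  structure(list(left = left, right = right, bottom = bottom, top = top),
            class = "exo_transport_bc")
}

#' Reconstruct the advected face value from an upwind-biased stencil
#'
#' Pure scheme kernel used by the flux assembly; exposed for testing and
#' illustration. All arguments vectorize.
#'
#' @param c_farup value two cells upwind of the face.
#' @param c_up value one cell upwind (the donor cell).
#' @param c_down value one cell downwind.
#' @param scheme,limiter see [transportParams()].
#' @return reconstructed concentration at the face.
#' @export
faceValue <- function(c_farup, c_up, c_down,
                      scheme = c("muscl", "upwind1", "upwind2", "quick"),
                      limiter = c("minmod", "vanleer")) {
  scheme <- match.arg(scheme)
  limiter <- match.arg(limiter)
  switch(scheme,
    upwind1 = c_up,
    upwind2 = 1.5 * c_up - 0.5 * c_farup,
    quick   = 0.375 * c_down + 0.75 * c_up - 0.125 * c_farup,
    muscl   = {
      a <- c_up - c_farup; b <- c_down - c_up
      s <- if (limiter == "minmod") {
        0.5 * (sign(a) + sign(b)) * pmin(abs(a), abs(b))
      } else {
        # van Leer: harmonic mean of one-sided slopes
        d <- a + b
        ifelse(a * b > 0, 2 * a * b / ifelse(d == 0, 1, d), 0)
      }
      c_up + 0.5 * s
    })
}

## internal: map side bc value to a vector at given coordinates/time
bcValues <- function(side, x, y, t) {
  v <- side$value
  if (is.function(v)) v(x, y, t) else rep_len(v, length(x))
}

#' Assemble a transport problem
#'
#' Precomputes face transmissibilities, open-face masks, the source
#' distribution and (for implicit diffusion) the factorized backward-Euler
#' operator, for repeated stepping at fixed \code{dt}.
#'
#' @param grid an \code{exo_grid}.
#' @param mask an \code{exo_mask} (see [rasterizeLayout()], [emptyMask()]).
#' @param velocity \code{NULL} (stagnant) or a list with face-normal
#'   velocities \code{uf} ((nx+1) x ny, m/s) and \code{vf} (nx x (ny+1)).
#' @param params an \code{exo_transport_params}.
#' @param sources list of \code{exo_source} objects (see [sourceSpec()]).
#' @param bc an \code{exo_transport_bc}.
#' @param dt time step (s); fixed over a run.
#' @param cfl_max advective CFL ceiling; exceeding it is an error
#'   (default 1, at which first-order upwind is exact in 1-D).
#' @return an environment of class \code{exo_transport_problem}.
#' @export
makeTransportProblem <- function(grid, mask, velocity = NULL, params,
                                 sources = list(), bc = transportBC(),
                                 dt, cfl_max = 1.0) {
  stopifnot(inherits(grid, "exo_grid"), inherits(mask, "exo_mask"),
            inherits(params, "exo_transport_params"))
  if (dt <= 0) stop("makeTransportProblem: dt must be positive", call. = FALSE)
  nx <- grid$nx; ny <- grid$ny
  fluid <- !mask$solid
  if (inherits(sources, "exo_source")) sources <- list(sources)

  # open-face masks (flux permitted)
  openx <- matrix(FALSE, nx + 1, ny)
  openy <- matrix(FALSE, nx, ny + 1)
  openx[2:nx, ] <- fluid[-nx, , drop = FALSE] & fluid[-1, , drop = FALSE]
  openy[, 2:ny] <- fluid[, -ny, drop = FALSE] & fluid[, -1, drop = FALSE]
  # boundary faces open for advection if the bc is not a wall
  if (bc$left$type   != "wall") openx[1, ]      <- fluid[1, ]
  if (bc$right$type  != "wall") openx[nx + 1, ] <- fluid[nx, ]
  if (bc$bottom$type != "wall") openy[, 1]      <- fluid[, 1]
  if (bc$top$type    != "wall") openy[, ny + 1] <- fluid[, ny]

  if (is.null(velocity)) {
    uf <- matrix(0, nx + 1, ny); vf <- matrix(0, nx, ny + 1)
  } else {
    uf <- velocity$uf; vf <- velocity$vf
    stopifnot(all(dim(uf) == c(nx + 1, ny)), all(dim(vf) == c(nx, ny + 1)))
  }
  Fxc <- uf * grid$Ax; Fxc[!openx] <- 0     # volumetric flux coefficients
  Fyc <- vf * grid$Ay; Fyc[!openy] <- 0
  cfl <- dt * (max(abs(uf)) / grid$dx + max(abs(vf)) / grid$dy)
  if (cfl > cfl_max * (1 + 1e-12))
    stop(sprintf("makeTransportProblem: advective CFL %.3g exceeds %.3g; reduce dt",
                 cfl, cfl_max), call. = FALSE)

  # source distribution: per-cell injection rate matrices, one per species
  Q <- replicate(params$n_species, matrix(0, nx, ny), simplify = FALSE)
  for (s in sources) {
    stopifnot(inherits(s, "exo_source"))
    q <- distributeSource(s, grid, mask)
    k <- s$species
    Q[[k]] <- Q[[k]] + q
  }

  # diffusive transmissibilities per open interior face: A / dist
  Tx <- grid$Ax / grid$dx; Tx[!openx] <- 0
  Ty <- grid$Ay / grid$dy; Ty[!openy] <- 0
  # boundary diffusive exchange only on dirichlet sides (half-cell distance)
  bfaces <- list()
  addb <- function(side, pos) {
    if (side$type != "dirichlet") return(NULL)
    if (pos == "left") {
      i <- which(fluid[1, ]); if (!length(i)) return(NULL)
      list(cells = cbind(1L, i), g = 2 * grid$Ax[1, i] / grid$dx,
           x = rep(grid$xf[1], length(i)), y = grid$yc[i], side = side)
    } else if (pos == "right") {
      i <- which(fluid[nx, ]); if (!length(i)) return(NULL)
      list(cells = cbind(nx, i), g = 2 * grid$Ax[nx + 1, i] / grid$dx,
           x = rep(grid$xf[nx + 1], length(i)), y = grid$yc[i], side = side)
    } else if (pos == "bottom") {
      i <- which(fluid[, 1]); if (!length(i)) return(NULL)
      list(cells = cbind(i, 1L), g = 2 * grid$Ay[i, 1] / grid$dy,
           x = grid$xc[i], y = rep(grid$yf[1], length(i)), side = side)
    } else {
      i <- which(fluid[, ny]); if (!length(i)) return(NULL)
      list(cells = cbind(i, ny), g = 2 * grid$Ay[i, ny + 1] / grid$dy,
           x = grid$xc[i], y = rep(grid$yf[ny + 1], length(i)), side = side)
    }
  }
  for (pos in c("left", "right", "bottom", "top")) {
    bf <- addb(bc[[pos]], pos)
    if (!is.null(bf)) bfaces[[pos]] <- bf
  }

  # fluid-cell indexing for the implicit operator
  fidx <- matrix(0L, nx, ny)
  fidx[fluid] <- seq_len(sum(fluid))
  nf <- sum(fluid)
  Vf <- grid$V[fluid]

  factors <- NULL; Kmats <- NULL; dt_stab <- Inf
  # assemble the (species-independent) diffusion stiffness pattern once
  ii <- jj <- vv <- list(); nE <- 0L
  addFace <- function(p, q, g) {
    nE <<- nE + 1L
    ii[[nE]] <<- c(p, q, p, q); jj[[nE]] <<- c(p, q, q, p)
    vv[[nE]] <<- c(g, g, -g, -g)
  }
  # x-faces
  wx <- which(openx[2:nx, , drop = FALSE], arr.ind = TRUE)
  if (nrow(wx)) {
    fi <- wx[, 1] + 1L; j <- wx[, 2]
    p <- fidx[cbind(fi - 1L, j)]; q <- fidx[cbind(fi, j)]
    g <- Tx[cbind(fi, j)]
    addFace(p, q, g)
  }
  wy <- which(openy[, 2:ny, drop = FALSE], arr.ind = TRUE)
  if (nrow(wy)) {
    i <- wy[, 1]; fj <- wy[, 2] + 1L
    p <- fidx[cbind(i, fj - 1L)]; q <- fidx[cbind(i, fj)]
    g <- Ty[cbind(i, fj)]
    addFace(p, q, g)
  }
  K1 <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                             dims = c(nf, nf))
  # dirichlet boundary faces add to the diagonal
  bdiag <- numeric(nf); for (bf in bfaces) {
    p <- fidx[bf$cells]; bdiag[p] <- bdiag[p] + bf$g
  }
  Kfull <- K1 + Matrix::Diagonal(nf, bdiag)

  Mmats <- NULL; refine <- FALSE
  if (params$diffusion == "implicit") {
    # euler: backward-Euler over dt; heun: Crank-Nicolson over dt/2
    fdt <- if (params$integrator == "heun") dt / 4 else dt
    Mmats <- lapply(params$gamma, function(g)
      Matrix::Diagonal(nf, Vf) + fdt * g * Kfull)
    factors <- lapply(Mmats, Matrix::Cholesky, LDL = FALSE)
    # strongly diffusion-dominated operators (dt*gamma*A/d >> V) lose
    # ~eps * cond(M) of mass per direct solve; one iterative-refinement
    # pass restores conservation to round-off
    dom <- max(sapply(seq_along(Mmats), function(k)
      fdt * params$gamma[k] * max(Matrix::diag(Kfull) / Vf)))
    refine <- dom > 100
  } else {
    # explicit stability: dt <= min_i V_i / (gamma * sum_f A_f/d)
    denom <- Matrix::diag(Kfull)
    dt_stab <- min(Vf / (max(params$gamma) * pmax(denom, .Machine$double.xmin)))
    if (dt > dt_stab * (1 + 1e-12))
      stop(sprintf("makeTransportProblem: explicit diffusion unstable: dt = %.3g > %.3g",
                   dt, dt_stab), call. = FALSE)
  }

  prob <- new.env(parent = emptyenv())
  prob$grid <- grid; prob$mask <- mask; prob$params <- params
  prob$bc <- bc; prob$dt <- dt; prob$cfl <- cfl
  prob$uf <- uf; prob$vf <- vf
  prob$Fxc <- Fxc; prob$Fyc <- Fyc
  prob$posx <- (uf >= 0) * 1; prob$posy <- (vf >= 0) * 1
  prob$openx <- openx; prob$openy <- openy
  prob$Tx <- Tx; prob$Ty <- Ty
  prob$bfaces <- bfaces
  prob$fluid <- fluid; prob$fidx <- fidx; prob$Vf <- Vf; prob$nf <- nf
  prob$Q <- Q
  prob$Kfull <- Kfull; prob$factors <- factors
  prob$Mmats <- Mmats; prob$refine <- refine
  class(prob) <- "exo_transport_problem"
  prob
}

#' Exosome source specification
#'
#' A total release rate distributed uniformly (area-weighted over SOURCE
#' faces, or volume-weighted over a cell region) so the distributed
#' contributions sum to the prescribed rate exactly.
#'
#' @param rate total release rate, exosomes/s (>= 0).
#' @param faces list with logical matrices \code{fx} ((nx+1) x ny) and/or
#'   \code{fy} (nx x (ny+1)) flagging release faces, or \code{NULL}.
#' @param cells logical nx x ny matrix of release cells, or \code{NULL}.
#' @param species species index the source feeds (default 1).
#' @export
sourceSpec <- function(rate, faces = NULL, cells = NULL, species = 1L) {
  if (rate < 0) stop("sourceSpec: rate must be >= 0", call. = FALSE)
  if (is.null(faces) && is.null(cells))
    stop("sourceSpec: provide faces or cells", call. = FALSE)
  structure(list(rate = rate, faces = faces, cells = cells,
                 species = as.integer(species)),
            class = "exo_source")
}

## internal: turn a source spec into a per-cell injection-rate matrix
distributeSource <- function(s, grid, mask) {
  nx <- grid$nx; ny <- grid$ny
  q <- matrix(0, nx, ny)
  if (s$rate == 0) return(q)
  fluid <- !mask$solid
  if (!is.null(s$cells)) {
    w <- grid$V * (s$cells & fluid)
    if (sum(w) == 0) stop("sourceSpec: empty source cell region", call. = FALSE)
    return(s$rate * w / sum(w))
  }
  # face sources: each flagged face feeds its adjacent FLUID cell,
  # area-weighted (uniform flux over the release surface)
  wcell <- matrix(0, nx, ny)
  fx <- s$faces$fx; fy <- s$faces$fy
  if (!is.null(fx)) {
    wf <- which(fx, arr.ind = TRUE)
    for (r in seq_len(nrow(wf))) {
      fi <- wf[r, 1]; j <- wf[r, 2]; a <- grid$Ax[fi, j]
      iL <- fi - 1L; iR <- fi
      if (iL >= 1 && fluid[iL, j]) wcell[iL, j] <- wcell[iL, j] + a
      else if (iR <= nx && fluid[iR, j]) wcell[iR, j] <- wcell[iR, j] + a
    }
  }
  if (!is.null(fy)) {
    wf <- which(fy, arr.ind = TRUE)
    for (r in seq_len(nrow(wf))) {
      i <- wf[r, 1]; fj <- wf[r, 2]; a <- grid$Ay[i, fj]
      jB <- fj - 1L; jT <- fj
      if (jB >= 1 && fluid[i, jB]) wcell[i, jB] <- wcell[i, jB] + a
      else if (jT <= ny && fluid[i, jT]) wcell[i, jT] <- wcell[i, jT] + a
    }
  }
  if (sum(wcell) == 0)
    stop("sourceSpec: no source face adjoins a FLUID cell", call. = FALSE)
  s$rate * wcell / sum(wcell)
}

## internal: padded array with two ghost layers filled per bc (advection)
padConcentration <- function(c, prob, t) {
  nx <- prob$grid$nx; ny <- prob$grid$ny
  cp <- matrix(0, nx + 4, ny + 4)
  cp[3:(nx + 2), 3:(ny + 2)] <- c
  fill <- function(side, pos) {
    if (side$type == "dirichlet") {
      if (pos == "left") {
        b <- bcValues(side, rep(prob$grid$xf[1], ny), prob$grid$yc, t)
        cp[1, 3:(ny + 2)] <<- b; cp[2, 3:(ny + 2)] <<- b
      } else if (pos == "right") {
        b <- bcValues(side, rep(prob$grid$xf[nx + 1], ny), prob$grid$yc, t)
        cp[nx + 3, 3:(ny + 2)] <<- b; cp[nx + 4, 3:(ny + 2)] <<- b
      } else if (pos == "bottom") {
        b <- bcValues(side, prob$grid$xc, rep(prob$grid$yf[1], nx), t)
        cp[3:(nx + 2), 1] <<- b; cp[3:(nx + 2), 2] <<- b
      } else {
        b <- bcValues(side, prob$grid$xc, rep(prob$grid$yf[ny + 1], nx), t)
        cp[3:(nx + 2), ny + 3] <<- b; cp[3:(nx + 2), ny + 4] <<- b
      }
    } else if (side$type == "outflow") {
      if (pos == "left") cp[1:2, 3:(ny + 2)] <<- rbind(c[1, ], c[1, ])
      else if (pos == "right") cp[(nx + 3):(nx + 4), 3:(ny + 2)] <<-
          rbind(c[nx, ], c[nx, ])
      else if (pos == "bottom") cp[3:(nx + 2), 1:2] <<- cbind(c[, 1], c[, 1])
      else cp[3:(nx + 2), (ny + 3):(ny + 4)] <<- cbind(c[, ny], c[, ny])
    }
  }
  for (pos in c("left", "right", "bottom", "top")) fill(prob$bc[[pos]], pos)
  cp
}

## internal: advective flux divergence (net outflow, exosomes/s per cell)
advectiveNetOutflow <- function(c, prob, t) {
  nx <- prob$grid$nx; ny <- prob$grid$ny
  cp <- padConcentration(c, prob, t)
  cols <- 3:(ny + 2)
  cL2 <- cp[1:(nx + 1), cols, drop = FALSE]
  cL1 <- cp[2:(nx + 2), cols, drop = FALSE]
  cR1 <- cp[3:(nx + 3), cols, drop = FALSE]
  cR2 <- cp[4:(nx + 4), cols, drop = FALSE]
  px <- prob$posx; sch <- prob$params$scheme; lim <- prob$params$limiter
  cU  <- px * cL1 + (1 - px) * cR1
  cUU <- px * cL2 + (1 - px) * cR2
  cD  <- px * cR1 + (1 - px) * cL1
  Fx <- prob$Fxc * faceValue(cUU, cU, cD, sch, lim)
  rows <- 3:(nx + 2)
  cB2 <- cp[rows, 1:(ny + 1), drop = FALSE]
  cB1 <- cp[rows, 2:(ny + 2), drop = FALSE]
  cT1 <- cp[rows, 3:(ny + 3), drop = FALSE]
  cT2 <- cp[rows, 4:(ny + 4), drop = FALSE]
  py <- prob$posy
  cU  <- py * cB1 + (1 - py) * cT1
  cUU <- py * cB2 + (1 - py) * cT2
  cD  <- py * cT1 + (1 - py) * cB1
  Fy <- prob$Fyc * faceValue(cUU, cU, cD, sch, lim)
  net <- (Fx[2:(nx + 1), , drop = FALSE] - Fx[1:nx, , drop = FALSE]) +
         (Fy[, 2:(ny + 1), drop = FALSE] - Fy[, 1:ny, drop = FALSE])
  # advective outflow across the outer boundary (for balance monitors)
  bnd_out <- sum(Fx[nx + 1, ]) - sum(Fx[1, ]) + sum(Fy[, ny + 1]) - sum(Fy[, 1])
  list(net = net, boundary_outflow = bnd_out)
}

## internal: dirichlet boundary exchange vector gamma * g2 * b(t) over
## fluid cells, and the matching per-cell coefficient gamma * g2
boundaryVec <- function(prob, g, t) {
  bvec <- numeric(prob$nf)
  for (bf in prob$bfaces) {
    p <- prob$fidx[bf$cells]
    bv <- bcValues(bf$side, bf$x, bf$y, t)
    bvec[p] <- bvec[p] + g * bf$g * bv
  }
  bvec
}

## internal: direct solve of the implicit operator, with one
## iterative-refinement pass for diffusion-dominated cases
solveImplicit <- function(prob, k, rhs) {
  cf <- as.numeric(Matrix::solve(prob$factors[[k]], rhs))
  if (prob$refine) {
    r <- rhs - as.numeric(prob$Mmats[[k]] %*% cf)
    cf <- cf + as.numeric(Matrix::solve(prob$factors[[k]], r))
  }
  cf
}

## internal: diffusive net outflow per cell in flux form (each face flux
## enters its two cells with exactly opposite sign, so the cell sums
## telescope and global conservation holds to round-off), plus the total
## outflow through dirichlet boundary faces
diffusiveNetOutflow <- function(c, prob, g, t) {
  nx <- prob$grid$nx; ny <- prob$grid$ny
  Fx <- matrix(0, nx + 1, ny)
  Fx[2:nx, ] <- g * prob$Tx[2:nx, , drop = FALSE] *
    (c[1:(nx - 1), , drop = FALSE] - c[2:nx, , drop = FALSE])
  Fy <- matrix(0, nx, ny + 1)
  Fy[, 2:ny] <- g * prob$Ty[, 2:ny, drop = FALSE] *
    (c[, 1:(ny - 1), drop = FALSE] - c[, 2:ny, drop = FALSE])
  net <- (Fx[2:(nx + 1), , drop = FALSE] - Fx[1:nx, , drop = FALSE]) +
         (Fy[, 2:(ny + 1), drop = FALSE] - Fy[, 1:ny, drop = FALSE])
  bout <- 0
  for (bf in prob$bfaces) {
    bv <- bcValues(bf$side, bf$x, bf$y, t)
    fo <- g * bf$g * (c[bf$cells] - bv)
    net[bf$cells] <- net[bf$cells] + fo
    bout <- bout + sum(fo)
  }
  list(net = net, boundary_outflow = bout)
}

## internal: backward-Euler diffusion over dt, applied in flux form
beDiffusion <- function(prob, k, cstar, tn) {
  g <- prob$params$gamma[k]
  bvec <- boundaryVec(prob, g, tn)
  rhs <- prob$Vf * cstar[prob$fluid] + prob$dt * bvec
  ctil <- matrix(0, prob$grid$nx, prob$grid$ny)
  ctil[prob$fluid] <- solveImplicit(prob, k, rhs)
  dno <- diffusiveNetOutflow(ctil, prob, g, tn)
  cn <- cstar - (prob$dt / prob$grid$V) * dno$net
  cn[prob$mask$solid] <- 0
  list(c = cn, outflow = dno$boundary_outflow)
}

## internal: Crank-Nicolson diffusion over dt/2, applied in flux form
cnHalfStep <- function(prob, k, c, t_mid) {
  g <- prob$params$gamma[k]
  dth <- prob$dt / 2
  d0 <- diffusiveNetOutflow(c, prob, g, t_mid)
  bvec <- boundaryVec(prob, g, t_mid)
  rhs <- prob$Vf * c[prob$fluid] - (dth / 2) * g *
    as.numeric(prob$Kfull %*% c[prob$fluid]) + dth * bvec
  ctil <- matrix(0, prob$grid$nx, prob$grid$ny)
  ctil[prob$fluid] <- solveImplicit(prob, k, rhs)
  d1 <- diffusiveNetOutflow(ctil, prob, g, t_mid)
  cn <- c - (dth / prob$grid$V) * (d0$net + d1$net) / 2
  cn[prob$mask$solid] <- 0
  list(c = cn,
       outflow = (d0$boundary_outflow + d1$boundary_outflow) / 2)
}

#' Advance the transport state by one step
#'
#' One conservative finite-volume update: advective fluxes with the
#' configured reconstruction scheme, source injection, and diffusion,
#' combined by the configured time integrator (first-order IMEX Euler or
#' second-order Strang/Heun).
#'
#' @param prob problem from [makeTransportProblem()].
#' @param c concentration state: nx x ny matrix (one species) or list of
#'   matrices.
#' @param t time at the start of the step (s).
#' @return list with \code{c} (updated state, same shape), \code{t}, and
#'   \code{diag}: per-species boundary advective/diffusive outflow (exosomes/s)
#'   and injected source rate.
#' @export
stepTransport <- function(prob, c, t) {
  single <- is.matrix(c)
  cl <- if (single) list(c) else c
  dt <- prob$dt
  V <- prob$grid$V
  out <- vector("list", length(cl))
  adv_out <- dif_out <- src_in <- numeric(length(cl))
  heun <- prob$params$integrator == "heun" &&
    prob$params$diffusion == "implicit"
  for (k in seq_along(cl)) {
    ck <- cl[[k]]
    if (any(!is.finite(ck)))
      stop("stepTransport: non-finite concentration entering step at t = ", t,
           call. = FALSE)
    g <- prob$params$gamma[k]
    tn <- t + dt
    if (heun) {
      h1 <- cnHalfStep(prob, k, ck, t + dt / 4)
      c1 <- h1$c
      a1 <- advectiveNetOutflow(c1, prob, t)
      F1 <- (prob$Q[[k]] - a1$net) / V
      ca <- c1 + dt * F1; ca[prob$mask$solid] <- 0
      a2 <- advectiveNetOutflow(ca, prob, tn)
      F2 <- (prob$Q[[k]] - a2$net) / V
      c2 <- c1 + (dt / 2) * (F1 + F2); c2[prob$mask$solid] <- 0
      h2 <- cnHalfStep(prob, k, c2, t + 3 * dt / 4)
      cn <- h2$c
      adv_out[k] <- (a1$boundary_outflow + a2$boundary_outflow) / 2
      dif_out[k] <- (h1$outflow + h2$outflow) / 2
    } else {
      adv <- advectiveNetOutflow(ck, prob, t)
      cstar <- ck - (dt / V) * adv$net + (dt / V) * prob$Q[[k]]
      cstar[prob$mask$solid] <- 0
      if (prob$params$diffusion == "implicit") {
        be <- beDiffusion(prob, k, cstar, tn)
        cn <- be$c
        dif_out[k] <- be$outflow
      } else {
        dno <- diffusiveNetOutflow(cstar, prob, g, tn)
        cn <- cstar - (dt / V) * dno$net
        cn[prob$mask$solid] <- 0
        dif_out[k] <- dno$boundary_outflow
      }
      adv_out[k] <- adv$boundary_outflow
    }
    if (any(!is.finite(cn)))
      stop("stepTransport: numerical failure (non-finite result) at t = ", tn,
           " dt = ", dt, " scheme = ", prob$params$scheme, call. = FALSE)
    out[[k]] <- cn
    src_in[k] <- sum(prob$Q[[k]])
  }
  list(c = if (single) out[[1]] else out, t = t + dt,
       diag = list(advective_outflow = adv_out, diffusive_outflow = dif_out,
                   source_rate = src_in))
}

#' Integrated exosome count of a field
#'
#' Sum of concentration times cell volume over FLUID cells (volumes
#' include the out-of-plane depth on 2-D Cartesian grids).
#'
#' @param c nx x ny concentration matrix.
#' @param grid an \code{exo_grid}.
#' @param mask an \code{exo_mask} (optional; default all fluid).
#' @return total exosome count (dimensionless).
#' @export
totalMass <- function(c, grid, mask = NULL) {
  if (is.null(mask)) return(sum(c * grid$V))
  sum((c * grid$V)[!mask$solid])
}

#' Run a transport simulation
#'
#' Fixed-step time integration with per-step monitors (total mass,
#' boundary balance, optional plane-flux and region monitors) and field
#' checkpoints.
#'
#' @param prob problem from [makeTransportProblem()].
#' @param c0 initial state (matrix, list of matrices, or scalar 0).
#' @param t0 start time (s).
#' @param t_end end time (s); the step count is
#'   \code{round((t_end - t0)/dt)} and must match \code{dt} exactly.
#' @param monitors optional named list; each element one of
#'   \code{list(type = "yplane_flux", j = <face index>, i = <cell cols>)}
#'   (cumulative diffusive flux upward through y-face plane j) or
#'   \code{list(type = "region_mean", cells = <logical matrix>)}.
#' @param n_checkpoints number of equispaced field checkpoints (>= 1;
#'   the final state is always checkpointed).
#' @return object of class \code{exo_transport_history}: \code{times},
#'   \code{mass} (per species columns), \code{monitors} data.frame,
#'   \code{checkpoints} (list of \code{t}, \code{c}), \code{final},
#'   cumulative boundary outflows and injected totals.
#' @export
runTransport <- function(prob, c0 = 0, t0 = 0, t_end, monitors = list(),
                         n_checkpoints = 1L) {
  nx <- prob$grid$nx; ny <- prob$grid$ny
  nsp <- prob$params$n_species
  if (is.numeric(c0) && length(c0) == 1)
    c0 <- replicate(nsp, matrix(c0, nx, ny), simplify = FALSE)
  if (is.matrix(c0)) c0 <- list(c0)
  stopifnot(length(c0) == nsp)
  dt <- prob$dt
  nsteps <- round((t_end - t0) / dt)
  if (abs(nsteps * dt - (t_end - t0)) > 1e-9 * max(1, abs(t_end - t0)))
    stop("runTransport: (t_end - t0) must be an integer multiple of dt",
         call. = FALSE)
  ck_at <- unique(pmax(1L, round(seq_len(n_checkpoints) * nsteps / n_checkpoints)))
  times <- numeric(nsteps)
  mass <- matrix(0, nsteps, nsp)
  adv_out <- dif_out <- src_in <- matrix(0, nsteps, nsp)
  mon_vals <- lapply(monitors, function(m) numeric(nsteps))
  mon_cum <- lapply(monitors, function(m) 0)
  checkpoints <- list()
  cl <- c0
  t <- t0
  g1 <- prob$params$gamma[1]
  for (n in seq_len(nsteps)) {
    st <- stepTransport(prob, cl, t)
    cl <- st$c; t <- st$t
    times[n] <- t
    for (k in seq_len(nsp)) mass[n, k] <- totalMass(cl[[k]], prob$grid, prob$mask)
    adv_out[n, ] <- st$diag$advective_outflow
    dif_out[n, ] <- st$diag$diffusive_outflow
    src_in[n, ] <- st$diag$source_rate
    if (length(monitors)) {
      c1 <- cl[[1]]
      for (mn in seq_along(monitors)) {
        m <- monitors[[mn]]
        if (m$type == "yplane_flux") {
          i <- if (is.null(m$i)) seq_len(nx) else m$i
          j <- m$j
          flx <- sum(g1 * prob$Ty[cbind(i, j)] *
                       (c1[cbind(i, j - 1L)] - c1[cbind(i, j)]))
          mon_cum[[mn]] <- mon_cum[[mn]] + flx * dt
          mon_vals[[mn]][n] <- mon_cum[[mn]]
        } else if (m$type == "region_mean") {
          sel <- m$cells & !prob$mask$solid
          mon_vals[[mn]][n] <- sum((c1 * prob$grid$V)[sel]) / sum(prob$grid$V[sel])
        } else if (m$type == "region_total") {
          sel <- m$cells & !prob$mask$solid
          mon_vals[[mn]][n] <- sum((c1 * prob$grid$V)[sel])
        } else stop("runTransport: unknown monitor type ", m$type, call. = FALSE)
      }
    }
    if (n %in% ck_at)
      checkpoints[[length(checkpoints) + 1L]] <-
        list(t = t, c = if (nsp == 1) cl[[1]] else cl)
  }
  mon_df <- data.frame(time_s = times)
  for (mn in seq_along(monitors)) mon_df[[names(monitors)[mn]]] <- mon_vals[[mn]]
  structure(list(times = times, mass = mass,
                 monitors = mon_df,
                 advective_outflow = adv_out, diffusive_outflow = dif_out,
                 source_rate = src_in, dt = dt, t0 = t0,
                 checkpoints = checkpoints,
                 final = if (nsp == 1) cl[[1]] else cl),
            class = "exo_transport_history")
}

#' @export
print.exo_transport_history <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<exo_transport_history> %d steps, t in [%.4g, %.4g] s, final mass %.6g\n",
              n, x$t0, x$times[n], x$mass[n, 1]))
  invisible(x)
}
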