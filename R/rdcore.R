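# species bookkeeping: cytosol carries free Ca + 4 mobile/stationary
# buffers, SR carries free Ca + calsequestrin
CYT_BUFFERS <- 1:4
CSQ <- 5L

#' Initialize the field state
#'
#' Free calcium is uniform at its resting value in each domain and every
#' buffer starts at binding equilibrium, so all reaction terms vanish at
#' t = 0.
#'
#' @param grid a [build_grid()] object.
#' @param params parameter list ([default_params()]).
#' @return a `field_state`: full-grid vectors `c`, `s`, and a list `b` of
#'   five bound-buffer fields (values are zero outside the species'
#'   domain), plus `t`.
#' @export
init_state <- function(grid, params) {
  stopifnot(inherits(grid, "cru_grid"))
  n3 <- grid$n^3
  cyt <- which(grid$labels == LAB_CYT)
  sr <- which(grid$labels == LAB_JSR | grid$labels == LAB_NSR)
  bf <- params$buffers
  tr <- params$transport
  beq <- function(i, cc) bf$kon[i] * cc * bf$Btot[i] / (bf$kon[i] * cc + bf$koff[i])
  st <- list(c = numeric(n3), s = numeric(n3),
             b = replicate(5, numeric(n3), simplify = FALSE), t = 0)
  st$c[cyt] <- tr$resting_c
  st$s[sr] <- tr$resting_s
  for (i in CYT_BUFFERS) st$b[[i]][cyt] <- beq(i, tr$resting_c)
  st$b[[CSQ]][sr] <- beq(CSQ, tr$resting_s)
  structure(st, class = "field_state")
}

# voxel index sets per domain
domain_voxels <- function(grid, domain) {
  if (domain == "cytosol") which(grid$labels == LAB_CYT)
  else which(grid$labels == LAB_JSR | grid$labels == LAB_NSR)
}

#' Diffusion step for all species
#'
#' Seven-point Laplacian on each diffusing species restricted to its own
#' domain; internal SR/cytosol walls are no-flux (membrane exchange is a
#' separate operator).  The outer cube boundary is either sealed or
#' clamped to the resting composition.  `method = "explicit"` substeps a
#' forward-time scheme to satisfy the stability bound; `method = "cn"`
#' uses Crank-Nicolson with a cached sparse factorization (accurate for
#' desk-scale verification grids).
#'
#' @param state a [init_state()] field state.
#' @param grid the grid.
#' @param params parameter list.
#' @param dt time step, ms.
#' @param method `"explicit"` or `"cn"` (default from
#'   `params$numerics$diffusion`).
#' @return updated state.
#' @export
diffusion_step <- function(state, grid, params, dt,
                           method = params$numerics$diffusion) {
  bcode <- boundary_code(params$numerics)
  bf <- params$buffers
  tr <- params$transport
  beq <- function(i, cc) bf$kon[i] * cc * bf$Btot[i] / (bf$kon[i] * cc + bf$koff[i])
  species <- list(
    list(field = "c", buffer = NA, dom = 0L, D = tr$D_c, clamp = tr$resting_c),
    list(field = "s", buffer = NA, dom = 1L, D = tr$D_s, clamp = tr$resting_s))
  for (i in CYT_BUFFERS)
    species <- c(species, list(list(field = "b", buffer = i, dom = 0L,
                                    D = bf$D[i], clamp = beq(i, tr$resting_c))))
  # calsequestrin is stationary (D = 0); nothing to do for it
  for (sp in species) {
    if (sp$D <= 0) next
    f <- if (is.na(sp$buffer)) state[[sp$field]] else state$b[[sp$buffer]]
    f <- if (method == "explicit") {
      cpp_diffuse(f, as.integer(grid$labels), grid$n, sp$dom, sp$D,
                  grid$dx_um, dt, bcode, sp$clamp)
    } else {
      cn_diffuse(f, grid, sp$dom, sp$D, dt, bcode, sp$clamp)
    }
    if (is.na(sp$buffer)) state[[sp$field]] <- f else state$b[[sp$buffer]] <- f
  }
  bad <- c(state$c[domain_voxels(grid, "cytosol")],
           state$s[domain_voxels(grid, "sr")])
  if (any(bad < -1e-9))
    stop("diffusion produced negative concentrations; reduce dt (instability)")
  state
}

# Crank-Nicolson step; factorization cached per (grid, domain, D, dt,
# boundary) in an environment attached to the grid's labels object.
cn_cache <- new.env(parent = emptyenv())

cn_diffuse <- function(f, grid, dom, D, dt, bcode, clamp) {
  key <- paste(format(grid$n), dom, format(D, digits = 12),
               format(dt, digits = 12), bcode,
               format(grid$serca_area_um2, digits = 12), grid$dx_nm,
               sep = "|")
  ent <- cn_cache[[key]]
  if (is.null(ent)) {
    L <- domain_laplacian(grid, dom, bcode)   # includes boundary diag term
    vox <- L$vox
    r <- D / grid$dx_um^2
    A <- Matrix::Diagonal(length(vox)) - (dt * r / 2) * L$L
    B <- Matrix::Diagonal(length(vox)) + (dt * r / 2) * L$L
    ent <- list(vox = vox, A = A, B = B, nclamp = L$nclamp,
                fac = Matrix::lu(A), r = r)
    cn_cache[[key]] <- ent
  }
  u <- f[ent$vox]
  # clamped outer faces contribute a constant source on both half-steps
  src <- dt * ent$r * clamp * ent$nclamp
  u_new <- as.numeric(Matrix::solve(ent$fac, ent$B %*% u + src))
  f[ent$vox] <- u_new
  f
}

# sparse graph Laplacian of one domain; reflecting internal walls, and in
# clamped mode an extra -1 on the diagonal per outer face (the ghost value
# enters as a source term)
domain_laplacian <- function(grid, dom, bcode) {
  n <- grid$n
  lab <- as.integer(grid$labels)
  in_dom <- if (dom == 0L) lab == LAB_CYT else lab == LAB_JSR | lab == LAB_NSR
  vox <- which(in_dom)
  slot <- integer(n^3)
  slot[vox] <- seq_along(vox)
  x <- ((vox - 1L) %% n); y <- ((vox - 1L) %/% n) %% n; z <- (vox - 1L) %/% (n * n)
  ii <- jj <- integer(0)
  deg <- numeric(length(vox))
  nclamp <- numeric(length(vox))
  shifts <- rbind(c(1L,0L,0L), c(-1L,0L,0L), c(0L,1L,0L),
                  c(0L,-1L,0L), c(0L,0L,1L), c(0L,0L,-1L))
  for (d in seq_len(6)) {
    xx <- x + shifts[d, 1]; yy <- y + shifts[d, 2]; zz <- z + shifts[d, 3]
    inside <- xx >= 0L & xx < n & yy >= 0L & yy < n & zz >= 0L & zz < n
    nb <- integer(length(vox))
    nb[inside] <- slot[xx[inside] + n * (yy[inside] + n * zz[inside]) + 1L]
    hit <- inside & nb > 0L
    ii <- c(ii, which(hit)); jj <- c(jj, nb[hit])
    deg <- deg + as.numeric(hit)
    if (bcode == 1L) nclamp <- nclamp + as.numeric(!inside)
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(vox), length(vox))) -
    Matrix::Diagonal(length(vox), deg + nclamp)
  list(L = L, vox = vox, nclamp = nclamp)
}

#' Buffer reaction step
#'
#' Per-voxel calcium-buffer binding update: every buffer relaxes along the
#' exact solution of its linear binding ODE with free calcium frozen at a
#' midpoint estimate (second-order accurate), and each change is
#' subtracted from the free pool, so the per-voxel total (free + bound)
#' is preserved exactly.
#'
#' @param state field state.
#' @param grid the grid.
#' @param params parameter list.
#' @param dt step, ms.
#' @param n_sub optional internal substeps (finer integration at the same
#'   total horizon; used by convergence checks).
#' @return updated state.
#' @export
reaction_step <- function(state, grid, params, dt, n_sub = 1L) {
  stopifnot(dt > 0)
  bf <- params$buffers
  cyt <- domain_voxels(grid, "cytosol")
  sr <- domain_voxels(grid, "sr")
  out <- cpp_buffer_step(state$c, state$b[CYT_BUFFERS], cyt,
                         bf$kon[CYT_BUFFERS], bf$koff[CYT_BUFFERS],
                         bf$Btot[CYT_BUFFERS], dt / n_sub, as.integer(n_sub))
  state$c <- out$c
  state$b[CYT_BUFFERS] <- out$b
  if (length(sr)) {
    out <- cpp_buffer_step(state$s, state$b[CSQ], sr, bf$kon[CSQ],
                           bf$koff[CSQ], bf$Btot[CSQ], dt / n_sub,
                           as.integer(n_sub))
    state$s <- out$c
    state$b[[CSQ]] <- out$b[[1]]
  }
  for (i in seq_len(5)) {
    bi <- state$b[[i]]
    if (any(bi < -1e-9 | bi > bf$Btot[i] + 1e-9))
      stop("bound buffer outside [0, Btot]")
  }
  state
}

#' SERCA flux density
#'
#' Steady-state cycling rate of a three-state pump scaled to a flux
#' density (uM um / ms, uptake-positive).  The rate is continuous in
#' (c, s), strictly increasing in cytosolic calcium at fixed luminal
#' calcium, and vanishes on the thermodynamic equilibrium locus
#' `c = s * sqrt(k1m k2m k3m / (k1p k2p k3p))`.
#'
#' @param c cytosolic free calcium, uM (vectorized).
#' @param s luminal free calcium, uM.
#' @param serca SERCA parameter block (see [default_params()]).
#' @export
serca_flux <- function(c, s, serca) {
  stopifnot(all(c >= 0), all(s >= 0))
  n <- max(length(c), length(s))
  serca$vmax * cpp_serca_rate(rep_len(as.numeric(c), n),
                              rep_len(as.numeric(s), n),
                              serca$k1p, serca$k2p, serca$k3p,
                              serca$k1m, serca$k2m, serca$k3m)
}

#' Equilibrium locus of the SERCA cycle
#'
#' Cytosolic calcium at which the pump flux vanishes for a given luminal
#' calcium.
#' @param s luminal free calcium, uM.
#' @param serca SERCA parameter block.
#' @export
serca_equilibrium_c <- function(s, serca) {
  s * sqrt((serca$k1m * serca$k2m * serca$k3m) /
             (serca$k1p * serca$k2p * serca$k3p))
}

#' Membrane flux step
#'
#' Applies the stiff SR/cytosol exchange over `dt`: each open channel's
#' flux `nu_ryr (s_adj - c_adj)` is spread over its footprint faces and
#' each face's adjoining voxel pair is advanced by the analytic solution
#' of the two-compartment exchange (the concentration difference decays
#' exponentially), so calcium is conserved across the membrane exactly.
#' The same flux law applies to phosphorylated and unphosphorylated
#' channels; their difference lives upstream in the opening rate.  SERCA
#' uptake is applied on the nSR faces.
#'
#' @param state field state.
#' @param grid the grid.
#' @param open logical per channel; closed channels contribute nothing.
#' @param params parameter list.
#' @param dt step, ms.
#' @param serca_on apply the pump flux (default TRUE).
#' @return updated state.
#' @export
membrane_flux_step <- function(state, grid, open, params, dt,
                               serca_on = TRUE) {
  tr <- params$transport
  Vvox <- grid$dx_um^3
  for (k in which(open)) {
    faces_c <- grid$ryr_cyt[[k]]
    faces_s <- grid$ryr_sr[[k]]
    g <- tr$nu_ryr / (Vvox * length(faces_c))
    out <- cpp_pair_exchange(state$c, state$s, faces_c, faces_s, g, dt)
    state$c <- out$c
    state$s <- out$s
  }
  if (serca_on && nrow(grid$serca_faces) > 0 && tr$serca$vmax > 0) {
    ic <- grid$serca_faces[, "cyt"]
    is <- grid$serca_faces[, "sr"]
    J <- serca_flux(state$c[ic], state$s[is], tr$serca)
    d <- J * grid$dx_um^2 * dt / Vvox
    d <- pmin(d, state$c[ic])
    d <- pmax(d, -state$s[is])
    state$c[ic] <- state$c[ic] - d
    state$s[is] <- state$s[is] + d
  }
  if (any(state$c < -1e-9) || any(state$s < -1e-9))
    stop("membrane flux produced negative concentrations")
  state
}

#' Total calcium in the domain
#'
#' Free plus bound calcium over both domains (uM * um^3); constant over a
#' sealed simulation.
#' @param state field state.
#' @param grid the grid.
#' @export
total_calcium <- function(state, grid) {
  Vvox <- grid$dx_um^3
  tot <- state$c + state$s
  for (i in seq_len(5)) tot <- tot + state$b[[i]]
  sum(tot) * Vvox
}

#' Run one spark simulation
#'
#' Starts from the resting state with one channel forced open (chosen
#' uniformly with R's RNG unless given), then advances by operator
#' splitting -- diffusion, buffering, membrane fluxes every `dt`, channel
#' gating every `dt_gate` -- until every channel has been closed for
#' 1 ms (the termination criterion; spark duration = last closure + 1 ms)
#' or the hard time cap is hit, in which case the record is flagged
#' `capped` rather than raising an error.  The fluorescence trace is the
#' maximum of the bound-dye field, optionally blurred with a Gaussian
#' point-spread function, sampled every `record_dt`.
#'
#' @param grid a [build_grid()] object.
#' @param assignment a [make_assignment()] object with K values (may be
#'   NULL for an unphosphorylated run).
#' @param params parameter list ([default_params()]).
#' @param init_channel channel forced open at t = 0 (default: uniform
#'   draw).
#' @return a `spark_record`: `times`, `F`, `dFF0`, `open_intervals`,
#'   `termination_time`, `capped`, `initiating_channel`, and the final
#'   field state (`final_state`).  With
#'   `params$numerics$store_fields = TRUE` the raw free-calcium and
#'   bound-dye fields of every recorded frame are kept in `fields`
#'   (lists `c` and `b4`, one full-grid vector per entry of `times`).
#' @export
run_spark <- function(grid, assignment = NULL, params = default_params(),
                      init_channel = NULL) {
  stopifnot(inherits(grid, "cru_grid"))
  nch <- grid$layout$n_ryr
  if (is.null(assignment)) {
    Kplus <- rep(K_NONPHOS, nch)
  } else {
    stopifnot(inherits(assignment, "phospho_assignment"))
    if (is.null(assignment$K_plus))
      stop("assignment has no K values; call assign_K() first")
    Kplus <- assignment$K_plus
  }
  if (is.null(init_channel)) init_channel <- sample.int(nch, 1)
  psf <- psf_voxels(params$numerics, grid)
  nm <- params$numerics
  par_cpp <- list(
    buffers = params$buffers,
    transport = params$transport,
    gating = c(params$gating),
    numerics = list(dt = nm$dt, dt_gate = nm$dt_gate, t_max = nm$t_max,
                    record_dt = nm$record_dt,
                    terminate_after = nm$terminate_after,
                    boundary = boundary_code(nm),
                    psf_on = psf$on, psf_sigma_vox = psf$sigma,
                    psf_radius_vox = psf$radius,
                    store_fields = isTRUE(nm$store_fields)))
  raw <- cpp_run_spark(as.integer(grid$labels), grid$n, grid$dx_um,
                       grid$ryr_cyt, grid$ryr_sr, Kplus,
                       grid$serca_faces[, "cyt"], grid$serca_faces[, "sr"],
                       par_cpp, init_channel - 1L)
  F0 <- raw$F[1]
  if (F0 <= 0) stop("baseline fluorescence is zero; check Fluo-4 parameters")
  final_state <- structure(list(c = raw$final_c, s = raw$final_s,
                                b = raw$final_b, t = raw$termination_time),
                           class = "field_state")
  structure(list(
    times = raw$times,
    F = raw$F,
    dFF0 = (raw$F - F0) / F0,
    open_intervals = raw$open_intervals,
    termination_time = raw$termination_time,
    capped = raw$capped,
    initiating_channel = init_channel,
    seed = NA_integer_,
    final_state = final_state,
    fields = raw$fields   # per-frame c and bound-dye fields, if requested
  ), class = "spark_record")
}

#' @export
print.spark_record <- function(x, ...) {
  cat(sprintf(
    "<spark_record: peak dF/F0 %.3f, duration %.2f ms, %d/%d channels opened%s>\n",
    max(x$dFF0), x$termination_time,
    sum(vapply(x$open_intervals, nrow, 1L) > 0), length(x$open_intervals),
    if (isTRUE(x$capped)) " [capped]" else ""))
  invisible(x)
}
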