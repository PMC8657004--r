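#' Boundary conditions for the bioheat solver
#'
#' Three kinds are supported per surface class: \code{robin} (convective flux
#' \code{h * (T_ext - T_surface)}, the water-bolus model), \code{dirichlet}
#' (fixed temperature) and \code{adiabatic} (zero flux). Surface classes are
#' \code{bolus} (exterior faces of bolus-contact voxels), \code{exterior}
#' (all other exterior faces) and \code{inactive} (faces against thermally
#' inactive labeled tissue such as lung or internal air).
#'
#' @param h heat-transfer coefficient (W m^-2 K^-1), robin only.
#' @param T_ext external temperature (degrees C).
#' @return a boundary-condition list.
#' @name boundary_conditions
NULL

#' @rdname boundary_conditions
#' @export
bc_robin <- function(h, T_ext) {
  if (!is.finite(h) || h < 0) stop("heat-transfer coefficient must be >= 0")
  if (!is.finite(T_ext)) stop("T_ext must be finite")
  list(kind = "robin", h = h, T_ext = T_ext)
}

#' @rdname boundary_conditions
#' @export
bc_dirichlet <- function(T_ext) {
  if (!is.finite(T_ext)) stop("T_ext must be finite")
  list(kind = "dirichlet", T_ext = T_ext)
}

#' @rdname boundary_conditions
#' @export
bc_adiabatic <- function() list(kind = "adiabatic")

#' @rdname boundary_conditions
#' @param bolus condition on exterior faces of bolus-contact voxels.
#' @param exterior condition on remaining exterior faces; treatment
#'   simulations default to adiabatic (applicator-enclosed patient), bench
#'   experiments typically use Robin to room air.
#' @param inactive condition at interfaces with inactive labeled tissue
#'   (default Dirichlet at 37 degrees C).
#' @export
bc_set <- function(bolus = bc_adiabatic(), exterior = bc_adiabatic(),
                   inactive = bc_dirichlet(37)) {
  structure(list(bolus = bolus, exterior = exterior, inactive = inactive),
            class = "bc_set")
}

#' Temperature field container
#' @param T 3D array of temperatures (degrees C); NA outside the domain.
#' @param time simulation time in seconds, or \code{Inf} for steady state.
#' @param iterations,residual solver diagnostics.
#' @return a \code{temperature_field} object.
#' @export
temperature_field <- function(T, time = Inf, iterations = NA_integer_,
                              residual = NA_real_) {
  structure(list(T = T, time = time, iterations = iterations, residual = residual),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  rng <- range(x$T, na.rm = TRUE)
  cat(sprintf("temperature_field: %s, range %.3f..%.3f degC, %s iteration(s)\n",
              if (is.infinite(x$time)) "steady" else sprintf("t = %.1f s", x$time),
              rng[1], rng[2],
              ifelse(is.na(x$iterations), "?", x$iterations)))
  invisible(x)
}

# Solve the SPD system A x = b: sparse direct (CHOLMOD/LU) for small systems,
# Jacobi-preconditioned conjugate gradients with optional warm start above
# `direct_limit` unknowns. Contract: relative residual below `tol`.
linear_solve <- function(A, b, x0 = NULL, tol = 1e-10, maxit = 5000L,
                         direct_limit = 4000L) {
  n <- length(b)
  if (n <= direct_limit) return(as.numeric(Matrix::solve(A, b)))
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(numeric(n))
  Minv <- 1 / Matrix::diag(A)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  r <- b - as.numeric(A %*% x)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    if (sqrt(sum(r^2)) <= tol * bnorm) return(x)
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate-gradient solver did not converge within ", maxit, " iterations")
}

# Discretize the Pennes equation with a 7-point finite-volume stencil.
# Returns the conduction operator K (sparse, symmetric, W/K), the boundary
# source b_bc (W), per-unknown property vectors, and the index maps. Face
# conductance between unknowns is the harmonic mean of k times voxel edge;
# boundary faces couple through the half-cell conduction resistance in series
# with the convective film (Robin) or the half cell alone (Dirichlet).
build_system <- function(phantom, props, blood, model, bcs,
                         props_eff = effective_properties(props, model)) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(bcs, "bc_set"))
  labels <- phantom$labels
  d <- dim(labels)
  s <- phantom$spacing / 1000          # voxel edge (m)
  A_face <- s^2
  V <- s^3

  row_of <- match(names(phantom$legend), props_eff$tissue)
  if (anyNA(row_of)) {
    stop("unlabeled/unknown tissue in phantom: ",
         paste(names(phantom$legend)[is.na(row_of)], collapse = ", "))
  }
  tissue_of_id <- stats::setNames(row_of, phantom$legend)   # label id -> table row

  act <- active_mask(phantom, props_eff)
  act_lin <- which(act)
  n <- length(act_lin)
  if (n == 0L) stop("phantom has no thermally active voxels")
  uid <- array(0L, d)
  uid[act_lin] <- seq_len(n)

  prow <- tissue_of_id[as.character(labels[act_lin])]
  kvox <- props_eff$k[prow]
  rho <- props_eff$rho[prow]
  cvox <- props_eff$c[prow]
  omega <- props_eff$omega[prow]
  Q <- props_eff$Q[prow]
  tissue <- props_eff$tissue[prow]
  if (any(!is.finite(kvox))) stop("active voxel with undefined thermal conductivity")

  contact <- phantom$masks$bolus_contact
  if (is.null(contact)) contact <- array(FALSE, d)
  # face directions through which the bolus couples (default: any)
  contact_faces <- phantom$contact_faces
  face_is_contact <- function(off) {
    if (is.null(contact_faces)) return(TRUE)
    ax <- which(off != 0L)
    any(vapply(contact_faces, function(cf) cf[1] == ax && cf[2] == off[ax], logical(1)))
  }

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_G <- numeric(n)
  b_bc <- numeric(n)

  bc_face <- function(bc, k_here) {
    # per-face conductance (W/K) and external temperature; NULL if adiabatic
    if (bc$kind == "adiabatic") return(NULL)
    if (bc$kind == "robin") {
      if (bc$h <= 0) return(NULL)
      G <- A_face / (s / (2 * k_here) + 1 / bc$h)
    } else {
      G <- 2 * k_here * A_face / s
    }
    list(G = G, T_ext = bc$T_ext)
  }

  offsets <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                  c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  ijk <- arrayInd(act_lin, d)
  strides <- c(1L, d[1], d[1] * d[2])
  for (off in offsets) {
    nb_ijk1 <- ijk[, 1] + off[1]
    nb_ijk2 <- ijk[, 2] + off[2]
    nb_ijk3 <- ijk[, 3] + off[3]
    inb <- nb_ijk1 >= 1L & nb_ijk1 <= d[1] &
           nb_ijk2 >= 1L & nb_ijk2 <= d[2] &
           nb_ijk3 >= 1L & nb_ijk3 <= d[3]
    nb_lin <- rep(NA_integer_, n)
    nb_lin[inb] <- (nb_ijk1[inb] - 1L) * strides[1] +
                   (nb_ijk2[inb] - 1L) * strides[2] +
                   (nb_ijk3[inb] - 1L) * strides[3] + 1L
    nb_uid <- rep(0L, n)
    nb_uid[inb] <- uid[nb_lin[inb]]
    nb_lab <- rep(0L, n)
    nb_lab[inb] <- labels[nb_lin[inb]]

    internal <- nb_uid > 0L
    if (any(internal)) {
      k1 <- kvox[internal]
      k2 <- kvox[nb_uid[internal]]
      G <- ifelse(k1 + k2 > 0, 2 * k1 * k2 / (k1 + k2), 0) * s
      i_int <- which(internal)
      ii <- c(ii, i_int); jj <- c(jj, nb_uid[internal]); xx <- c(xx, -G)
      diag_G[i_int] <- diag_G[i_int] + G
    }

    ext_face <- !internal & (!inb | nb_lab == 0L)     # exterior air / out of grid
    inact_face <- !internal & inb & nb_lab > 0L       # labeled inactive tissue
    if (any(ext_face)) {
      is_bolus <- ext_face & contact[act_lin] & face_is_contact(off)
      for (cls in c("bolus", "exterior")) {
        sel <- if (cls == "bolus") is_bolus else (ext_face & !is_bolus)
        if (!any(sel)) next
        fb <- bc_face(bcs[[cls]], kvox[sel])
        if (is.null(fb)) next
        w <- which(sel)
        diag_G[w] <- diag_G[w] + fb$G
        b_bc[w] <- b_bc[w] + fb$G * fb$T_ext
      }
    }
    if (any(inact_face)) {
      fb <- bc_face(bcs$inactive, kvox[inact_face])
      if (!is.null(fb)) {
        w <- which(inact_face)
        diag_G[w] <- diag_G[w] + fb$G
        b_bc[w] <- b_bc[w] + fb$G * fb$T_ext
      }
    }
  }

  K <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_G), dims = c(n, n))
  # volumetric perfusion coefficient at SF = 1, times voxel volume (W/K)
  pv0 <- blood$rho_b * blood$c_b * rho * omega * 1e-6 / 60 * V
  list(K = Matrix::forceSymmetric(K), b_bc = b_bc, n = n, uid = uid,
       act_lin = act_lin, dims = d, V = V,
       kvox = kvox, rho = rho, cvox = cvox, omega = omega, Q = Q,
       tissue = tissue, pv0 = pv0, contact_lin = which(contact & act))
}

# SF per unknown at temperatures Tvec (degC)
sf_per_voxel <- function(sys, model, Tvec) {
  sf <- rep(1, sys$n)
  if (model$mode != "temperature_dependent") return(sf)
  for (tis in intersect(unique(sys$tissue), names(model$sf_breakpoints))) {
    sel <- sys$tissue == tis
    sf[sel] <- scaling_factor(model, tis, Tvec[sel])
  }
  sf
}

sar_values <- function(sar, sys) {
  if (is.null(sar)) return(numeric(sys$n))
  stopifnot(inherits(sar, "sar_field"))
  sar$power_scale * sar$sar[sys$act_lin]
}

# full-grid temperature array from the unknown vector, with inactive voxels at
# the inactive boundary temperature and exterior voxels NA
field_from_vector <- function(sys, phantom, bcs, Tvec) {
  out <- array(NA_real_, sys$dims)
  out[sys$act_lin] <- Tvec
  inact <- phantom$labels > 0L
  inact[sys$act_lin] <- FALSE
  if (any(inact) && bcs$inactive$kind != "adiabatic") {
    out[inact] <- bcs$inactive$T_ext
  }
  out
}

#' Assemble the discrete steady-state bioheat system
#'
#' Exposes the 7-point finite-volume discretization of the Pennes equation:
#' returns the sparse operator \code{A} (W/K) and right-hand side \code{b}
#' (W) such that \code{A T = b} yields the steady temperature at the active
#' voxels, with the perfusion scaling factor evaluated at \code{T_current}.
#'
#' @param phantom,props,blood,model,sar,bcs see [solve_steady()].
#' @param T_current temperature array or scalar at which SF is evaluated
#'   (default arterial blood temperature).
#' @return list with \code{A}, \code{b}, and the internal system description
#'   \code{sys} (index maps, per-voxel properties).
#' @export
assemble_system <- function(phantom, props, blood, model, sar = NULL,
                            bcs = bc_set(), T_current = NULL) {
  sys <- build_system(phantom, props, blood, model, bcs)
  Tvec <- if (is.null(T_current)) {
    rep(blood$T_b, sys$n)
  } else if (length(T_current) == 1L) {
    rep(T_current, sys$n)
  } else {
    T_current[sys$act_lin]
  }
  sf <- sf_per_voxel(sys, model, Tvec)
  pv <- sys$pv0 * sf
  A <- sys$K + Matrix::Diagonal(sys$n, pv)
  b <- sys$b_bc + pv * blood$T_b + sys$rho * (sar_values(sar, sys) + sys$Q) * sys$V
  list(A = A, b = b, sys = sys)
}

#' Steady-state Pennes bioheat solve
#'
#' Solves \eqn{0 = \nabla\cdot(k\nabla T) - SF\,\rho_b c_b \rho\omega (T-T_b)
#' + \rho SAR + \rho Q} on the active voxels. The constant-stress model is a
#' single sparse Cholesky solve; the temperature-dependent model re-evaluates
#' SF at the current iterate and iterates a damped fixed point until the
#' maximum temperature update falls below \code{tol}.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param props tissue property table.
#' @param blood [blood_properties()].
#' @param model [perfusion_model()].
#' @param sar optional [sar_field()] heat source.
#' @param bcs a [bc_set()].
#' @param tol fixed-point tolerance on max |dT| (degrees C).
#' @param max_iter fixed-point iteration cap.
#' @param damping fixed-point damping factor in (0, 1].
#' @param T_init optional initial temperature array/scalar for the iteration.
#' @return a [temperature_field()].
#' @export
solve_steady <- function(phantom, props, blood = blood_properties(),
                         model = perfusion_model("constant_stress"),
                         sar = NULL, bcs = bc_set(),
                         tol = 1e-3, max_iter = 100L, damping = 0.5,
                         T_init = NULL) {
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  sys <- build_system(phantom, props, blood, model, bcs)
  rhs_fixed <- sys$b_bc + sys$rho * (sar_values(sar, sys) + sys$Q) * sys$V

  warm <- if (!is.null(T_init) && length(T_init) > 1L) T_init[sys$act_lin]
          else if (!is.null(T_init)) rep(T_init, sys$n)
          else NULL
  solve_once <- function(sf) {
    pv <- sys$pv0 * sf
    A <- sys$K + Matrix::Diagonal(sys$n, pv)
    warm <<- linear_solve(A, rhs_fixed + pv * blood$T_b, x0 = warm)
    warm
  }

  temp_dep <- model$mode == "temperature_dependent" &&
    length(model$sf_breakpoints) > 0 && any(sys$tissue %in% names(model$sf_breakpoints))
  if (!temp_dep) {
    Tvec <- solve_once(rep(1, sys$n))
    return(temperature_field(field_from_vector(sys, phantom, bcs, Tvec),
                             iterations = 1L, residual = 0))
  }

  Tvec <- if (is.null(T_init)) rep(blood$T_b, sys$n)
          else if (length(T_init) == 1L) rep(T_init, sys$n)
          else T_init[sys$act_lin]
  resid <- Inf
  for (it in seq_len(max_iter)) {
    sf <- sf_per_voxel(sys, model, Tvec)
    Tnew <- solve_once(sf)
    resid <- max(abs(Tnew - Tvec))
    Tvec <- (1 - damping) * Tvec + damping * Tnew
    if (resid < tol) {
      return(temperature_field(field_from_vector(sys, phantom, bcs, Tvec),
                               iterations = it, residual = resid))
    }
  }
  stop(sprintf("temperature-dependent solve did not converge in %d iterations (last max |dT| = %.3g degC)",
               max_iter, resid))
}

#' Transient Pennes bioheat solve
#'
#' Advances \eqn{c\rho\,\partial T/\partial t} with the assembled operator,
#' either by unconditionally stable implicit (backward) Euler with a reused
#' sparse factorization, or by explicit Euler with a stability check. The
#' perfusion scaling factor is lagged one step for the temperature-dependent
#' model; when the operator is temperature-independent (constant-stress or
#' perfusion-free problems) the implicit factorization is computed once.
#'
#' @inheritParams solve_steady
#' @param T_init initial temperature: scalar or full-grid array (degrees C).
#' @param duration total simulated time (s).
#' @param dt time step (s).
#' @param sample_times times (s) at which fields are returned; defaults to
#'   \code{c(0, duration)}. Times off the step grid are linearly interpolated.
#' @param scheme \code{"implicit"} (default) or \code{"explicit"}.
#' @return object of class \code{transient_result}: list with \code{times} and
#'   \code{fields} (list of [temperature_field()]).
#' @export
solve_transient <- function(phantom, props, blood = blood_properties(),
                            model = perfusion_model("constant_stress"),
                            sar = NULL, bcs = bc_set(),
                            T_init = 37, duration, dt,
                            sample_times = NULL,
                            scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!is.finite(duration) || duration < 0) stop("duration must be >= 0")
  if (is.null(sample_times)) sample_times <- c(0, duration)
  sample_times <- sort(unique(pmin(sample_times, duration)))
  if (any(sample_times < 0)) stop("sample times must be >= 0")

  sys <- build_system(phantom, props, blood, model, bcs)
  rhs_fixed <- sys$b_bc + sys$rho * (sar_values(sar, sys) + sys$Q) * sys$V
  Mdiag <- sys$rho * sys$cvox * sys$V          # J/K per voxel
  Tvec <- if (length(T_init) == 1L) rep(T_init, sys$n) else T_init[sys$act_lin]

  temp_dep <- model$mode == "temperature_dependent" &&
    any(sys$tissue %in% names(model$sf_breakpoints)) && any(sys$pv0 > 0)

  operator <- function(sf) {
    pv <- sys$pv0 * sf
    list(A = sys$K + Matrix::Diagonal(sys$n, pv), b = rhs_fixed + pv * blood$T_b)
  }

  nstep <- if (duration == 0) 0L else ceiling(duration / dt - 1e-9)
  if (scheme == "explicit" && nstep > 0L) {
    op <- operator(sf_per_voxel(sys, model, Tvec))
    dt_max <- min(Mdiag / Matrix::diag(op$A))
    if (dt > dt_max) {
      stop(sprintf("explicit scheme unstable: dt = %.4g s exceeds the stability bound %.4g s",
                   dt, dt_max))
    }
  }

  store <- vector("list", length(sample_times))
  prev_T <- Tvec; prev_t <- 0
  record <- function(Tnow, tnow) {
    # emit any sample times passed during (prev_t, tnow]
    for (si in seq_along(sample_times)) {
      st <- sample_times[si]
      if (!is.null(store[[si]])) next
      if (st <= tnow + 1e-9) {
        w <- if (tnow > prev_t) (st - prev_t) / (tnow - prev_t) else 1
        store[[si]] <<- (1 - w) * prev_T + w * Tnow
      }
    }
  }
  record(Tvec, 0)

  if (nstep > 0L) {
    if (scheme == "implicit") {
      op <- operator(sf_per_voxel(sys, model, Tvec))
      lhs <- Matrix::Diagonal(sys$n, Mdiag / dt) + op$A
      for (step in seq_len(nstep)) {
        if (temp_dep) {
          op <- operator(sf_per_voxel(sys, model, Tvec))
          lhs <- Matrix::Diagonal(sys$n, Mdiag / dt) + op$A
        }
        rhs <- Mdiag / dt * Tvec + op$b
        prev_T <- Tvec; prev_t <- (step - 1) * dt
        Tvec <- linear_solve(lhs, rhs, x0 = Tvec)
        record(Tvec, min(step * dt, duration))
      }
    } else {
      for (step in seq_len(nstep)) {
        op <- if (temp_dep || step == 1L) operator(sf_per_voxel(sys, model, Tvec)) else op
        prev_T <- Tvec; prev_t <- (step - 1) * dt
        Tvec <- Tvec + dt / Mdiag * (op$b - as.numeric(op$A %*% Tvec))
        record(Tvec, min(step * dt, duration))
      }
    }
  }
  record(Tvec, duration)

  fields <- mapply(function(v, t) {
    temperature_field(field_from_vector(sys, phantom, bcs, v), time = t)
  }, store, sample_times, SIMPLIFY = FALSE)
  structure(list(times = sample_times, fields = fields),
            class = "transient_result")
}

#' Trilinear interpolation of a temperature (or any voxel) field
#'
#' @param field 3D array on the phantom grid.
#' @param phantom the \code{voxel_phantom} defining the grid geometry.
#' @param positions n x 3 matrix of world coordinates (mm).
#' @return numeric vector of interpolated values.
#' @export
sample_field <- function(field, phantom, positions) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  d <- dim(field)
  fr <- sweep(sweep(positions, 2, phantom$origin, `-`), 2, rep(phantom$spacing, 3), `/`) + 1
  if (any(fr < 1 - 1e-9) || any(sweep(fr, 2, d, `-`) > 1e-9)) {
    stop("sample position outside the phantom grid")
  }
  fr <- pmin(pmax(fr, 1), matrix(rep(d, each = nrow(fr)), ncol = 3))
  i0 <- pmin(floor(fr), matrix(rep(d - 1L, each = nrow(fr)), ncol = 3))
  i0 <- pmax(i0, 1)
  w <- fr - i0
  out <- numeric(nrow(fr))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (cx * w[, 1] + (1 - cx) * (1 - w[, 1])) *
          (cy * w[, 2] + (1 - cy) * (1 - w[, 2])) *
          (cz * w[, 3] + (1 - cz) * (1 - w[, 3]))
    vals <- field[cbind(i0[, 1] + cx, i0[, 2] + cy, i0[, 3] + cz)]
    out <- out + wt * vals
  }
  out
}
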