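# Quasi-static electrical model: RF current at ~500 kHz behaves
# resistively at tissue scale, so the potential solves
# div(sigma grad V) = 0 with Dirichlet values on the energized tines and
# the return pad, and zero normal current elsewhere. The generator's
# control loop is not simulated: the recorded power is imposed by
# rescaling a unit-potential solve each control step.

#' Solve the quasi-static RF potential
#'
#' Solves \code{div(sigma grad V) = 0} with \code{V = electrode_potential}
#' on the energized electrode surface, \code{V = 0} on the ground
#' boundary, and insulated (zero normal current) exterior faces.
#'
#' For electrodes whose features sit at the grid scale (a thin tine, a
#' millimetre sphere), the lattice under-resolves the near-field
#' spreading resistance. The assembler therefore calibrates the
#' electrode boundary couplings against a local fine-grid solve around
#' the electrode (see \code{\link{calibrate_electrode_coupling}});
#' disable with \code{near_field_calibration = FALSE}.
#'
#' @param domain an \code{rfa_domain}.
#' @param conductivity electrical conductivity in S/m (scalar or per-node
#'   vector).
#' @param electrode_potential applied potential in volts.
#' @param op optional pre-assembled operator (reused across control steps
#'   while the conductivity is unchanged).
#' @param x0 warm-start potential field.
#' @param tol relative residual tolerance of the linear solve.
#' @param near_field_calibration calibrate electrode couplings by a
#'   local subgrid solve (ignored when \code{op} is supplied).
#' @param cascade on large grids, warm-start from a solve at twice the
#'   spacing (trilinearly prolonged).
#' @return Full-grid potential vector (V) with attributes
#'   \code{operator}, \code{electrode_potential}, \code{iter},
#'   \code{relres}.
#' @export
solve_potential <- function(domain, conductivity, electrode_potential = 1,
                            op = NULL, x0 = NULL, tol = 1e-7,
                            near_field_calibration = TRUE,
                            cascade = TRUE) {
  if (!length(domain$labels$ground))
    stop("domain has no ground boundary: the electrical system is singular")
  if (!length(domain$labels$electrode_surface))
    stop("domain has no electrode surface")
  if (is.null(op)) {
    op <- assemble_diffusion_operator(
      domain, conductivity,
      dirichlet = list(electrode_surface = 1, ground = 0))
    if (near_field_calibration) {
      s <- calibrate_electrode_coupling(domain, conductivity)
      op <- scale_electrode_coupling(op, s)
    }
  }
  # two-grid cascade: on large grids, warm-start from a solve at twice
  # the spacing (prolonged piecewise-constant), which cuts the CG
  # iteration count several-fold
  if (is.null(x0) && cascade && prod(domain$dims) > 1.5e6 &&
      !is.null(domain$scene)) {
    coarse <- discretize_scene(domain$scene, 2 * domain$spacing)
    sig_c <- if (length(conductivity) == 1L) conductivity
    else sigma_by_material(domain, conductivity)$lookup(coarse$material)
    Vc <- solve_potential(coarse, sig_c, electrode_potential,
                          tol = max(tol, 1e-6),
                          near_field_calibration = near_field_calibration,
                          cascade = TRUE)
    x0 <- prolong_field(coarse, domain, as.numeric(Vc))
    x0[!op$unknown] <- 0
    rm(Vc, coarse)
    gc(FALSE)
  }
  # Dirichlet load scales linearly with the applied potential
  if (electrode_potential == 0) {
    V <- numeric(prod(domain$dims))
    attr(V, "iter") <- 0L
  } else {
    V <- solve_operator(op, rhs = op$b * electrode_potential, x0 = x0,
                        tol = tol)
  }
  attr(V, "operator") <- op
  attr(V, "electrode_potential") <- electrode_potential
  V
}

#' Dissipated power density of a potential field
#'
#' Computes the Joule heating \code{sigma |grad V|^2} from the discrete
#' link fluxes: the power dissipated on each grid link is
#' \code{c (V_i - V_j)^2} (with \code{c} the link conductance), split
#' between its end cells; boundary-link power is assigned to the interior
#' cell. The domain integral of the resulting density equals the total
#' dissipated power identically, so energy bookkeeping is exact.
#'
#' @param potential potential field from \code{\link{solve_potential}}.
#' @param conductivity conductivity used for the solve (only needed when
#'   \code{op} must be re-assembled).
#' @param domain the domain (idem).
#' @param op operator override; defaults to the one attached to
#'   \code{potential}.
#' @return An \code{electrical_state}: \code{potential},
#'   \code{power_density} (W/m^3 per cell), \code{power_W} (W per cell),
#'   \code{total_power} (W), \code{effective_impedance} (Ohm),
#'   \code{electrode_potential} (V).
#' @export
power_density <- function(potential, conductivity = NULL, domain = NULL,
                          op = NULL) {
  if (is.null(op)) op <- attr(potential, "operator")
  if (is.null(op)) {
    if (is.null(domain) || is.null(conductivity))
      stop("need either an operator attribute or (domain, conductivity)")
    op <- assemble_diffusion_operator(
      domain, conductivity,
      dirichlet = list(electrode_surface = 1, ground = 0))
  }
  dom <- op$domain
  N <- prod(dom$dims)
  V <- as.numeric(potential)
  pw <- numeric(N)
  for (lk in op$links) {
    s <- lk$shift
    i <- which(lk$c != 0)
    if (!length(i)) next
    p <- lk$c[i] * (V[i] - V[i + s])^2
    pw[i] <- pw[i] + p / 2
    pw[i + s] <- pw[i + s] + p / 2
  }
  v0 <- attr(potential, "electrode_potential")
  for (dl in op$dir_links) {
    # the electrode Dirichlet value scales with the applied potential;
    # the ground stays at zero
    val <- if (dl$surface == "electrode_surface" && !is.null(v0)) v0 else dl$value
    p <- dl$c * (V[dl$idx] - val)^2
    pw[dl$idx] <- pw[dl$idx] + p
  }
  total <- sum(pw)
  vol <- (dom$spacing * 1e-3)^3
  imp <- if (!is.null(v0) && total > 0) v0^2 / total else NA_real_
  structure(list(potential = V, power_W = pw, power_density = pw / vol,
                 total_power = total, effective_impedance = imp,
                 electrode_potential = v0, domain = dom),
            class = "electrical_state")
}

#' @export
print.electrical_state <- function(x, ...) {
  cat(sprintf("electrical_state: %.3g W total at %.3g V (Z = %.1f Ohm)\n",
              x$total_power, x$electrode_potential, x$effective_impedance))
  invisible(x)
}

#' Rescale an electrical state to a recorded generator power
#'
#' Scales the power density by \code{target_power / total_power} and the
#' potential by the square root of that ratio, so the domain-integrated
#' dissipated power equals the recorded value exactly. The effective
#' impedance is unchanged (both V^2 and P scale together).
#'
#' @param state an \code{electrical_state}.
#' @param target_power recorded applied power in watts (>= 0).
#' @return The rescaled \code{electrical_state}.
#' @export
scale_to_recorded_power <- function(state, target_power) {
  stopifnot(inherits(state, "electrical_state"))
  if (target_power < 0) stop("target power must be >= 0")
  if (target_power == 0) {
    state$potential <- state$potential * 0
    state$power_W <- state$power_W * 0
    state$power_density <- state$power_density * 0
    state$total_power <- 0
    state$electrode_potential <- 0
    return(state)
  }
  if (state$total_power <= 0)
    stop("cannot scale: baseline dissipated power is zero")
  ratio <- target_power / state$total_power
  state$potential <- state$potential * sqrt(ratio)
  state$power_W <- state$power_W * ratio
  state$power_density <- state$power_density * ratio
  state$total_power <- target_power
  state$electrode_potential <- state$electrode_potential * sqrt(ratio)
  state
}

# Trilinear prolongation of a coarse-grid field onto a finer grid of
# the same scene (interpolating among the 8 surrounding coarse cell
# centers, clamped at the boundary).
prolong_field <- function(coarse, fine, values) {
  N <- prod(fine$dims)
  d <- coarse$dims
  out <- numeric(N)
  # chunked to bound peak memory on large grids
  chunk <- 2e6
  for (s in seq(1L, N, by = chunk)) {
    idx_f <- s:min(s + chunk - 1, N)
    co <- domain_coords(fine, idx_f)
    u <- sweep(co, 2L, coarse$origin) / coarse$spacing  # coarse index - 1
    lo <- floor(u)
    w <- u - lo
    acc <- numeric(length(idx_f))
    for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
      cx <- pmin(pmax(lo[, 1] + ox, 0), d[1] - 1L)
      cy <- pmin(pmax(lo[, 2] + oy, 0), d[2] - 1L)
      cz <- pmin(pmax(lo[, 3] + oz, 0), d[3] - 1L)
      idx <- cx + d[1] * cy + d[1] * d[2] * cz + 1L
      wt <- (if (ox) w[, 1] else 1 - w[, 1]) *
        (if (oy) w[, 2] else 1 - w[, 2]) *
        (if (oz) w[, 3] else 1 - w[, 3])
      acc <- acc + wt * values[idx]
    }
    out[idx_f] <- acc
  }
  out
}

# ---- near-field subgrid calibration -----------------------------------

#' Calibrate electrode boundary couplings by a local subgrid solve
#'
#' Electrode features at the grid scale (tine wires, small spheres)
#' concentrate most of the spreading resistance within one or two cells,
#' where a uniform lattice is least accurate. This routine performs the
#' standard subgrid-upscaling correction: it cuts a box around the
#' electrode, solves the local conduction problem twice — once on the
#' run grid and once at \code{refine}-fold finer spacing, both with unit
#' electrode potential and grounded box faces — and returns the factor
#' by which the coarse electrode Dirichlet couplings must be scaled so
#' the coarse local conductance matches the fine one. The common outer
#' boundary condition cancels to first order, so the factor captures the
#' coarse grid's near-field deficit only. The result is deterministic
#' and is computed without reference to any analytic solution.
#'
#' @param domain the run \code{rfa_domain}.
#' @param conductivity conductivity used for the run (scalar or field;
#'   a field is sampled per material class).
#' @param refine subgrid refinement factor.
#' @param margin_cells box margin around the electrode, in coarse cells.
#' @return the scalar coupling factor (>= 1 in practice).
#' @export
calibrate_electrode_coupling <- function(domain, conductivity,
                                         refine = 4L, margin_cells = 4L) {
  scene <- domain$scene
  h <- domain$spacing
  es <- scene$electrode_surface
  if (is.null(es)) return(1)
  # electrode bounding box + margin, clipped to the domain; the box
  # faces are grounded in both local problems, so their (common,
  # face-exact) outer condition cancels in the comparison
  bb <- if (es$type == "sphere")
    rbind(es$center - es$radius, es$center + es$radius)
  else apply(do.call(rbind, scene$electrode$tine_paths), 2L, range)
  lo <- bb[1, ] - margin_cells * h
  hi <- bb[2, ] + margin_cells * h
  dlo <- domain$origin - h / 2
  dhi <- domain$origin + h * (domain$dims - 0.5)
  lo <- pmax(lo, dlo); hi <- pmin(hi, dhi)
  r_cal <- max(hi - lo) / 2

  calib_scene <- new_scene(
    electrode = scene$electrode, electrode_surface = es,
    medium = list(type = "box", lo = lo, hi = hi),
    ground = list(type = "none"),
    vessels = scene$vessels, shaft = scene$shaft)

  # adapt the subgrid refinement to a fixed node budget: small
  # electrodes calibrate against a very fine local solve, large tine
  # arrays against the finest level that stays tractable
  n_est <- function(rf) (pi / 6) * (2 * r_cal * rf / h)^3
  refine <- as.integer(refine)
  while (refine > 2L && n_est(refine) > 3e6) refine <- refine - 1L
  while (refine < 8L && n_est(refine + 1L) < 1e6) refine <- refine + 1L

  sig <- sigma_by_material(domain, conductivity)
  faces0 <- list(face_xmin = 0, face_xmax = 0, face_ymin = 0,
                 face_ymax = 0, face_zmin = 0, face_zmax = 0)
  local_G <- function(res, scale = 1) {
    dom <- discretize_scene(calib_scene, res)
    kf <- sig$lookup(dom$material)
    op <- assemble_diffusion_operator(
      dom, kf, dirichlet = c(list(electrode_surface = 1), faces0))
    if (scale != 1) op <- scale_electrode_coupling(op, scale)
    V <- solve_operator(op, tol = 1e-8)
    attr(V, "electrode_potential") <- 1
    power_density(V, op = op)$total_power  # = conductance at 1 V
  }
  G_fine <- local_G(h / refine)
  # secant iteration on the coupling factor of the coarse local problem
  s <- 1
  G <- local_G(h, s)
  if (abs(G - G_fine) / G_fine < 1e-3) return(1)
  s2 <- s * max(min(G_fine / G, 8), 0.25)
  G2 <- local_G(h, s2)
  for (it in 1:8) {
    if (abs(G2 - G_fine) / G_fine < 1e-3) break
    ds <- (s2 - s) * (G_fine - G2) / (G2 - G)
    s <- s2; G <- G2
    s2 <- min(max(s2 + ds, 0.1), 20)
    G2 <- local_G(h, s2)
  }
  s2
}

sigma_by_material <- function(domain, conductivity) {
  N <- prod(domain$dims)
  k <- if (length(conductivity) == 1L) rep(conductivity, N) else conductivity
  per_mat <- vapply(MATERIALS, function(m) {
    sel <- domain$material == m
    if (any(sel)) stats::median(k[sel]) else NA_real_
  }, numeric(1))
  fallback <- stats::median(k[domain$material > 0L])
  per_mat[is.na(per_mat)] <- fallback
  list(lookup = function(mat) per_mat[match(mat, MATERIALS)])
}

#' Scale the electrode Dirichlet couplings of an assembled operator
#'
#' Multiplies the electrode-surface boundary conductances (diagonal and
#' load contributions) by a constant factor, as produced by
#' \code{\link{calibrate_electrode_coupling}}.
#' @param op an \code{rfa_operator} with an electrode Dirichlet surface.
#' @param s scaling factor.
#' @return the adjusted operator.
#' @export
scale_electrode_coupling <- function(op, s) {
  if (s == 1) return(op)
  for (j in seq_along(op$dir_links)) {
    dl <- op$dir_links[[j]]
    if (dl$surface != "electrode_surface") next
    extra <- (s - 1) * dl$c
    op$diag[dl$idx] <- op$diag[dl$idx] + extra
    op$b[dl$idx] <- op$b[dl$idx] + extra * dl$value
    op$dir_links[[j]]$c <- s * dl$c
  }
  attr(op, "electrode_coupling_scale") <- s
  op
}

# ---- generator power traces -------------------------------------------

#' Construct a power trace
#'
#' Time-stamped applied RF power at (nominally) 1 s cadence, as recorded
#' from the generator over a serial link during an ablation.
#'
#' @param time_s sample times in seconds, strictly increasing.
#' @param power_W applied power in watts (>= 0).
#' @param impedance_ohm optional recorded impedance in Ohm.
#' @return A \code{power_trace}.
#' @export
power_trace <- function(time_s, power_W, impedance_ohm = NULL) {
  n <- length(time_s)
  if (n == 0L) stop("empty power trace")
  if (length(power_W) != n) stop("time and power lengths differ")
  bad <- which(diff(time_s) <= 0)
  if (length(bad))
    stop(sprintf("power trace times not strictly increasing at row %d",
                 bad[1] + 1L))
  neg <- which(power_W < 0)
  if (length(neg))
    stop(sprintf("negative power at row %d", neg[1]))
  structure(list(time_s = as.numeric(time_s), power_W = as.numeric(power_W),
                 impedance_ohm = if (is.null(impedance_ohm)) NULL
                 else as.numeric(impedance_ohm)),
            class = "power_trace")
}

#' @export
print.power_trace <- function(x, ...) {
  cat(sprintf("power_trace: %d samples over %.0f s, %.0f-%.0f W\n",
              length(x$time_s), diff(range(x$time_s)),
              min(x$power_W), max(x$power_W)))
  invisible(x)
}

#' Read a generator power log
#'
#' CSV dialect \code{time_s,power_W[,impedance_ohm]}, UTF-8, '.' decimal,
#' with a header row. Rows must have strictly increasing times and
#' non-negative power; violations are reported with their row number.
#'
#' @param file path to the CSV log.
#' @return A \code{\link{power_trace}}.
#' @export
read_power_log <- function(file) {
  df <- read.csv(file)
  if (nrow(df) == 0L) stop("power log is empty: ", file)
  need <- c("time_s", "power_W")
  if (!all(need %in% names(df)))
    stop("power log must have columns time_s,power_W[,impedance_ohm]")
  power_trace(df$time_s, df$power_W,
              if ("impedance_ohm" %in% names(df)) df$impedance_ohm)
}

#' Write a generator power log
#' @param trace a \code{\link{power_trace}}.
#' @param file output CSV path.
#' @return \code{file}, invisibly.
#' @export
write_power_log <- function(trace, file) {
  df <- data.frame(time_s = sprintf("%.17g", trace$time_s),
                   power_W = sprintf("%.17g", trace$power_W))
  if (!is.null(trace$impedance_ohm))
    df$impedance_ohm <- sprintf("%.17g", trace$impedance_ohm)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Sample a power trace by zero-order hold
#'
#' The generator logs at 1 Hz; the solver may step faster. Each solver
#' step uses the most recent recorded sample (zero-order hold).
#'
#' @param trace a \code{\link{power_trace}}.
#' @param t query times in seconds.
#' @return power values in watts at \code{t}.
#' @export
resample_power <- function(trace, t) {
  idx <- findInterval(t, trace$time_s)
  idx[idx < 1L] <- 1L
  trace$power_W[idx]
}
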