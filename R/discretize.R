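# Structured-grid spatial discretization.
#
# The reference discretization is a cell-centered finite-volume scheme on a
# uniform hexahedral grid. Thin electrode surfaces (tines, analytic
# spheres) are embedded with sub-cell accuracy: nodes inside the energized
# surface are Dirichlet nodes, and for grid links crossing the surface the
# coupling uses the interface fraction theta obtained by linear
# interpolation of the signed distance, so the boundary position enters
# the stencil to O(h^2) rather than being snapped to the nearest node.

#' Discretize a scene into a structured simulation domain
#'
#' Builds a uniform cell-centered grid covering the scene medium, assigns
#' a material class to every cell (tissue/agar, vessel lumen, electrode
#' metal, insulated shaft, outside), stores the signed distance to the
#' energized electrode surface (and to an embedded spherical ground where
#' the scene has one), and collects the labelled boundary sets
#' \code{electrode_surface}, \code{ground}, \code{vessel_wall} and
#' \code{insulated_exterior}.
#'
#' @param scene an \code{rfa_scene}.
#' @param resolution grid spacing in mm (> 0 and smaller than the
#'   electrode nominal radius).
#' @return An \code{rfa_domain}: \code{dims}, \code{spacing} (mm),
#'   \code{origin} (mm, center of the first cell), \code{material}
#'   (integer vector, codes in \code{names(rfasim:::MATERIALS)}),
#'   \code{labels} (named integer index sets), \code{phi_e}/\code{phi_g}
#'   (signed distances, mm), \code{scene}.
#' @export
discretize_scene <- function(scene, resolution) {
  stopifnot(inherits(scene, "rfa_scene"))
  h <- resolution
  if (!is.finite(h) || h <= 0) stop("resolution must be > 0")
  if (!is.null(scene$electrode) &&
      h >= scene$electrode$nominal_diameter / 2)
    stop("resolution too coarse relative to the electrode radius")

  med <- scene$medium
  pad <- if (med$type == "ball" && scene$ground$type == "sphere") 2.5 * h else 0
  bbox <- switch(med$type,
    cylinder = list(lo = c(-med$radius, -med$radius, 0),
                    hi = c(med$radius, med$radius, med$height)),
    ball = list(lo = med$center - med$radius - pad,
                hi = med$center + med$radius + pad),
    box = list(lo = med$lo, hi = med$hi),
    stop("unknown medium type: ", med$type))
  dims <- pmax(2L, as.integer(ceiling((bbox$hi - bbox$lo) / h - 1e-9)))
  origin <- bbox$lo + h / 2
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  N <- prod(dims)

  xs <- origin[1] + h * (seq_len(nx) - 1L)
  ys <- origin[2] + h * (seq_len(ny) - 1L)
  zs <- origin[3] + h * (seq_len(nz) - 1L)
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)

  material <- integer(N)  # 0 = outside
  inside <- switch(med$type,
    cylinder = X^2 + Y^2 <= med$radius^2,
    ball = {
      r2 <- (X - med$center[1])^2 + (Y - med$center[2])^2 +
        (Z - med$center[3])^2
      r2 <= (med$radius + pad)^2
    },
    box = rep(TRUE, N))
  material[inside] <- MATERIALS[["tissue"]]

  # vessels: straight or polyline lumens
  for (v in scene$vessels) {
    cl <- v$centerline
    if (nrow(cl) == 2L && all(cl[1, 1:2] == cl[2, 1:2])) {
      # vertical channel: radial test is cheap
      din <- sqrt((X - cl[1, 1])^2 + (Y - cl[1, 2])^2) <= v$diameter / 2 &
        Z >= min(cl[, 3]) & Z <= max(cl[, 3])
    } else {
      bb <- apply(cl, 2L, range)
      m <- v$diameter / 2 + h
      cand <- which(inside & X >= bb[1, 1] - m & X <= bb[2, 1] + m &
                      Y >= bb[1, 2] - m & Y <= bb[2, 2] + m &
                      Z >= bb[1, 3] - m & Z <= bb[2, 3] + m)
      din <- rep(FALSE, N)
      if (length(cand))
        din[cand] <- dist_to_polyline(cbind(X[cand], Y[cand], Z[cand]),
                                      cl) <= v$diameter / 2
      din
    }
    material[inside & din] <- MATERIALS[["lumen"]]
  }

  # insulated shaft
  if (!is.null(scene$shaft)) {
    sh <- scene$shaft
    rs <- max(sh$radius, 0.6 * h)
    bb <- apply(rbind(sh$from, sh$to), 2L, range)
    cand <- which(inside & X >= bb[1, 1] - rs - h & X <= bb[2, 1] + rs + h &
                    Y >= bb[1, 2] - rs - h & Y <= bb[2, 2] + rs + h &
                    Z >= bb[1, 3] - rs - h & Z <= bb[2, 3] + rs + h)
    if (length(cand)) {
      ds <- dist_to_polyline(cbind(X[cand], Y[cand], Z[cand]),
                             rbind(sh$from, sh$to))
      material[cand[ds <= rs]] <- MATERIALS[["shaft"]]
    }
  }

  # energized electrode surface: signed distance phi_e near the electrode
  phi_e <- rep(Inf, N)
  es <- scene$electrode_surface
  if (is.null(es)) {
    # passive scene (analytic thermal cases): no energized surface
  } else if (es$type == "sphere") {
    phi_e <- sqrt((X - es$center[1])^2 + (Y - es$center[2])^2 +
                    (Z - es$center[3])^2) - es$radius
  } else if (es$type == "tines") {
    el <- scene$electrode
    allp <- do.call(rbind, el$tine_paths)
    bb <- apply(allp, 2L, range)
    r_eff <- max(es$tine_radius, 0.6 * h)
    m <- r_eff + 3 * h
    cand <- which(inside & X >= bb[1, 1] - m & X <= bb[2, 1] + m &
                    Y >= bb[1, 2] - m & Y <= bb[2, 2] + m &
                    Z >= bb[1, 3] - m & Z <= bb[2, 3] + m)
    if (length(cand))
      phi_e[cand] <- dist_to_tines(cbind(X[cand], Y[cand], Z[cand]), el) -
        r_eff
  } else stop("unknown electrode surface type: ", es$type)
  energized <- inside & phi_e <= 0 & material != MATERIALS[["lumen"]]
  material[energized] <- MATERIALS[["electrode"]]
  if (!is.null(es) && !any(energized))
    stop("discretization error: resolution too coarse, no electrode cells")

  # ground boundary
  phi_g <- NULL
  ground_idx <- integer(0)
  ground_type <- scene$ground$type
  if (ground_type == "sphere") {
    b <- scene$ground$radius
    rr <- sqrt((X - med$center[1])^2 + (Y - med$center[2])^2 +
                 (Z - med$center[3])^2)
    phi_g <- b - rr  # positive inside the grounded shell
    ground_idx <- which(material == MATERIALS[["tissue"]] & phi_g <= 0)
  } else if (ground_type == "bottom_pad") {
    iz1 <- seq_len(nx * ny)  # bottom cell layer
    inpad <- X[iz1]^2 + Y[iz1]^2 <= scene$ground$radius^2
    ground_idx <- iz1[inpad & material[iz1] %in%
                        MATERIALS[c("tissue", "lumen")]]
  } else if (ground_type != "none")
    stop("unknown ground type: ", ground_type)
  if (ground_type != "none" && !length(ground_idx))
    stop("scene has an empty ground boundary")

  dom <- structure(list(dims = dims, spacing = h, origin = origin,
                        material = material, phi_e = phi_e, phi_g = phi_g,
                        ground_type = ground_type,
                        labels = list(), scene = scene,
                        resolution = h),
                   class = "rfa_domain")

  conductive <- material %in% MATERIALS[c("tissue", "lumen")]
  unknown_e <- conductive
  unknown_e[ground_idx] <- ground_type == "bottom_pad"  # face-Dirichlet stays active
  dom$labels <- list(
    electrode_surface = which(material == MATERIALS[["electrode"]]),
    ground = ground_idx,
    vessel_wall = find_adjacent(dims, material == MATERIALS[["tissue"]],
                                material == MATERIALS[["lumen"]]),
    insulated_exterior = setdiff(
      find_adjacent(dims, material > 0L, material == 0L, include_box = TRUE),
      if (ground_type == "bottom_pad") ground_idx else integer(0)))
  dom
}

#' @export
print.rfa_domain <- function(x, ...) {
  cat(sprintf("rfa_domain: %d x %d x %d cells at %g mm (%d active)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              sum(x$material > 0L)))
  tab <- table(factor(names(MATERIALS)[match(x$material, MATERIALS)],
                      levels = names(MATERIALS)))
  print(tab)
  cat("labels:", paste(sprintf("%s=%d", names(x$labels),
                               lengths(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Cell-center coordinates of domain nodes
#' @param domain an \code{rfa_domain}.
#' @param idx optional linear node indices (default all).
#' @return n x 3 matrix of positions in mm.
#' @export
domain_coords <- function(domain, idx = NULL) {
  d <- domain$dims
  if (is.null(idx)) idx <- seq_len(prod(d))
  i0 <- idx - 1L
  ix <- i0 %% d[1]
  iy <- (i0 %/% d[1]) %% d[2]
  iz <- i0 %/% (d[1] * d[2])
  cbind(domain$origin[1] + domain$spacing * ix,
        domain$origin[2] + domain$spacing * iy,
        domain$origin[3] + domain$spacing * iz)
}

# Nodes in set A having a face neighbour in set B (logical masks).
# include_box: also counts the grid boundary itself as B.
find_adjacent <- function(dims, A, B, include_box = FALSE) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  N <- prod(dims)
  if (!any(B) && !include_box) return(integer(0))
  hit <- rep(FALSE, N)
  strides <- c(1L, nx, nx * ny)
  sizes <- c(nx, ny, nz)
  pos <- function(axis) {
    i0 <- seq_len(N) - 1L
    switch(axis, (i0 %% nx), ((i0 %/% nx) %% ny), (i0 %/% (nx * ny))) + 1L
  }
  for (ax in 1:3) {
    p <- pos(ax)
    s <- strides[ax]
    lo <- which(p < sizes[ax])
    up <- lo + s
    hit[lo] <- hit[lo] | (A[lo] & B[up])
    hit[up] <- hit[up] | (A[up] & B[lo])
    if (include_box) {
      edge <- which(p == 1L | p == sizes[ax])
      hit[edge] <- hit[edge] | A[edge]
    }
  }
  which(hit)
}

# ---- operator assembly ------------------------------------------------

# Stencil direction table: the classical face-neighbour finite-volume
# stencil. Links are stored on the lower-index node; the generic
# (shift, coupling) representation keeps the solver open to richer
# stencils.
st_directions <- function(dims) {
  nx <- dims[1]
  sxy <- nx * dims[2]
  list(list(d = c(1L, 0L, 0L), shift = 1L, w = 1),
       list(d = c(0L, 1L, 0L), shift = nx, w = 1),
       list(d = c(0L, 0L, 1L), shift = sxy, w = 1))
}

#' Assemble a conduction/diffusion operator on a domain
#'
#' Builds the symmetric finite-volume operator for
#' \code{-div(k grad u)} over the given unknown set, with harmonic-mean
#' link coefficients, Neumann (zero-flux) exterior faces, and Dirichlet
#' surfaces eliminated into the diagonal and load vector. Links crossing
#' an embedded Dirichlet surface are scaled by the sub-cell interface
#' fraction obtained from the domain's signed distance, so the boundary
#' position enters the stencil with sub-cell accuracy.
#'
#' All couplings are in SI conductance units (coefficient in S/m gives
#' Siemens; W/(m K) gives W/K): grid spacing is converted from mm.
#'
#' @param domain an \code{rfa_domain}.
#' @param coefficient positive coefficient per node (length-1 or full
#'   grid vector).
#' @param unknown logical mask of unknown nodes; default all conductive
#'   cells (tissue + lumen) that are not embedded-ground nodes.
#' @param dirichlet named list of boundary values, e.g.
#'   \code{list(electrode_surface = 1, ground = 0)}; names refer to the
#'   domain's labelled sets, or \code{face_xmin} ... \code{face_zmax}
#'   for values imposed on a whole grid face.
#' @return An \code{rfa_operator}: \code{links} (per-direction coupling
#'   arrays with their index shifts), \code{diag}, Dirichlet load
#'   \code{b}, the \code{unknown} mask, and \code{dir_links} recording
#'   boundary couplings for flux bookkeeping.
#' @export
assemble_diffusion_operator <- function(domain, coefficient,
                                        unknown = NULL, dirichlet = list()) {
  dims <- domain$dims
  N <- prod(dims)
  k <- if (length(coefficient) == 1L) rep(coefficient, N) else coefficient
  stopifnot(length(k) == N)
  act <- domain$material > 0L
  if (any(k[act] <= 0)) stop("coefficient must be positive on active cells")

  if (is.null(unknown)) {
    unknown <- domain$material %in% MATERIALS[c("tissue", "lumen")]
    if (domain$ground_type == "sphere")
      unknown[domain$labels$ground] <- FALSE
  }

  # Dirichlet masks and their interface distance fields
  dnames <- names(dirichlet)
  dmask <- vector("list", length(dirichlet)); names(dmask) <- dnames
  dphi <- vector("list", length(dirichlet)); names(dphi) <- dnames
  for (nm in dnames) {
    if (nm == "ground" && domain$ground_type == "bottom_pad") next
    if (startsWith(nm, "face_")) next
    m <- rep(FALSE, N)
    m[domain$labels[[nm]]] <- TRUE
    dmask[[nm]] <- m
    dphi[[nm]] <- switch(nm,
      electrode_surface = domain$phi_e,
      ground = if (!is.null(domain$phi_g)) domain$phi_g else NULL,
      NULL)
  }

  h_m <- domain$spacing * 1e-3
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  diagv <- numeric(N)
  b <- numeric(N)
  dir_links <- list()

  sizes <- c(nx, ny, nz)
  i0 <- seq_len(N) - 1L
  axpos <- list((i0 %% nx) + 1L, ((i0 %/% nx) %% ny) + 1L,
                (i0 %/% (nx * ny)) + 1L)
  dirs <- st_directions(dims)
  links <- vector("list", length(dirs))

  for (di in seq_along(dirs)) {
    dd <- dirs[[di]]
    valid <- rep(TRUE, N)
    for (ax in 1:3) {
      if (dd$d[ax] == 1L) valid <- valid & axpos[[ax]] < sizes[ax]
      else if (dd$d[ax] == -1L) valid <- valid & axpos[[ax]] > 1L
    }
    L <- which(valid)
    U <- L + dd$shift
    cc <- numeric(N)

    both <- unknown[L] & unknown[U]
    Lb <- L[both]; Ub <- U[both]
    cc[Lb] <- dd$w * h_m * 2 * k[Lb] * k[Ub] / (k[Lb] + k[Ub])

    for (nm in dnames) {
      if (is.null(dmask[[nm]])) next
      phi <- dphi[[nm]]
      val <- dirichlet[[nm]]
      for (side in 1:2) {
        ui <- if (side == 1L) L else U       # unknown side
        dv <- if (side == 1L) U else L       # Dirichlet side
        sel <- which(unknown[ui] & dmask[[nm]][dv])
        if (!length(sel)) next
        iu <- ui[sel]; id <- dv[sel]
        theta <- if (!is.null(phi)) {
          pu <- phi[iu]; pd <- phi[id]
          tt <- pu / (pu - pd)
          tt[!is.finite(tt)] <- 1
          pmin(pmax(tt, 0.05), 1)
        } else rep(1, length(sel))
        cdir <- dd$w * h_m * k[iu] / theta
        diagv[iu] <- diagv[iu] + cdir
        b[iu] <- b[iu] + cdir * val
        dir_links[[length(dir_links) + 1L]] <-
          list(surface = nm, idx = iu, c = cdir, value = val)
      }
    }
    links[[di]] <- list(shift = dd$shift, c = cc)
  }

  # face-Dirichlet boundaries: the value sits on the cell face, half a
  # cell from the boundary cell centers, giving the half-cell
  # conductance 2 k h.
  add_face <- function(fi, val, surface) {
    if (!length(fi)) return()
    cdir <- 2 * h_m * k[fi]
    diagv[fi] <<- diagv[fi] + cdir
    b[fi] <<- b[fi] + cdir * val
    dir_links[[length(dir_links) + 1L]] <<-
      list(surface = surface, idx = fi, c = cdir, value = val)
  }
  if ("ground" %in% dnames && domain$ground_type == "bottom_pad")
    add_face(intersect(domain$labels$ground, which(unknown)),
             dirichlet$ground, "ground")
  for (nm in grep("^face_", dnames, value = TRUE)) {
    ax <- match(substr(nm, 6L, 6L), c("x", "y", "z"))
    side <- substr(nm, 7L, 9L)
    fi <- which(unknown & axpos[[ax]] ==
                  if (side == "min") 1L else sizes[ax])
    add_face(fi, dirichlet[[nm]], nm)
  }

  # diagonal: sum of interior couplings plus Dirichlet couplings
  for (lk in links) {
    s <- lk$shift
    n <- N - s
    i <- seq_len(n)
    diagv[i] <- diagv[i] + lk$c[i]
    diagv[i + s] <- diagv[i + s] + lk$c[i]
  }

  structure(list(domain = domain, coefficient = k, unknown = unknown,
                 links = links, diag = diagv, b = b,
                 dir_links = dir_links),
            class = "rfa_operator")
}

#' Apply an assembled operator to a field
#' @param op an \code{rfa_operator}.
#' @param x full-grid numeric vector.
#' @return full-grid numeric vector \code{A x}.
#' @export
apply_operator <- function(op, x) {
  N <- prod(op$domain$dims)
  y <- op$diag * x
  for (lk in op$links) {
    s <- lk$shift
    i <- seq_len(N - s)
    y[i] <- y[i] - lk$c[i] * x[i + s]
    y[i + s] <- y[i + s] - lk$c[i] * x[i]
  }
  y[!op$unknown] <- 0
  y
}

#' Export the operator as a sparse matrix over its unknown nodes
#'
#' Useful for inspection and for small-domain tests (symmetry, row sums,
#' comparison against dense solves). Rows/columns follow
#' \code{which(op$unknown)} order.
#'
#' @param op an \code{rfa_operator}.
#' @return a \code{Matrix::dgCMatrix}.
#' @export
operator_matrix <- function(op) {
  N <- prod(op$domain$dims)
  uidx <- which(op$unknown)
  map <- integer(N)
  map[uidx] <- seq_along(uidx)
  ii <- list(); jj <- list(); vv <- list()
  for (lk in op$links) {
    s <- lk$shift
    i <- which(lk$c != 0)
    if (!length(i)) next
    ii[[length(ii) + 1L]] <- map[i]; jj[[length(jj) + 1L]] <- map[i + s]
    vv[[length(vv) + 1L]] <- -lk$c[i]
    ii[[length(ii) + 1L]] <- map[i + s]; jj[[length(jj) + 1L]] <- map[i]
    vv[[length(vv) + 1L]] <- -lk$c[i]
  }
  ii[[length(ii) + 1L]] <- map[uidx]; jj[[length(jj) + 1L]] <- map[uidx]
  vv[[length(vv) + 1L]] <- op$diag[uidx]
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(length(uidx), length(uidx)))
}

#' Solve the assembled system
#'
#' Matrix-free Jacobi-preconditioned conjugate gradients for
#' \code{A x = rhs}; the default right-hand side is the operator's
#' Dirichlet load vector.
#'
#' @param op an \code{rfa_operator}.
#' @param rhs right-hand side over the full grid (default \code{op$b}).
#' @param x0 warm-start field (default zeros).
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return full-grid solution vector with attributes \code{iter} and
#'   \code{relres}.
#' @export
solve_operator <- function(op, rhs = NULL, x0 = NULL, tol = 1e-8,
                           maxit = NULL) {
  d <- op$domain$dims
  N <- prod(d)
  if (is.null(rhs)) rhs <- op$b
  if (is.null(x0)) x0 <- numeric(N)
  if (is.null(maxit)) maxit <- max(3000L, 12L * max(d))
  rhs[!op$unknown] <- 0
  dg <- op$diag
  dg[!op$unknown] <- 0
  res <- .stencil_pcg(vapply(op$links, `[[`, numeric(1), "shift"),
                      lapply(op$links, `[[`, "c"), dg, rhs, x0,
                      tol, as.integer(maxit))
  if (res$relres > tol * 50)
    stop(sprintf("solver did not converge: relative residual %.3e after %d iterations",
                 res$relres, res$iter))
  x <- res$x
  attr(x, "iter") <- res$iter
  attr(x, "relres") <- res$relres
  x
}
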