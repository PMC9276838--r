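# Triangle meshes: iso-surface extraction (marching tetrahedra on the
# cell-centered grid), closed-surface volume/area, parametric spheres and
# half-ellipsoid unions, and PLY export. Meshes are oriented with
# outward normals so the divergence-theorem volume is positive.

tri_mesh <- function(vertices, triangles) {
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Enclosed volume of a closed oriented triangle mesh
#'
#' Divergence theorem: sum of signed tetrahedron volumes against the
#' origin; positive for outward-oriented closed surfaces.
#' @param mesh a \code{tri_mesh}.
#' @return volume in the cube of the vertex unit (mm^3 here).
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(0)
  v <- mesh$vertices
  a <- v[mesh$triangles[, 1], , drop = FALSE]
  b <- v[mesh$triangles[, 2], , drop = FALSE]
  c <- v[mesh$triangles[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Surface area of a triangle mesh
#' @param mesh a \code{tri_mesh}.
#' @return total area (mm^2).
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(0)
  v <- mesh$vertices
  e1 <- v[mesh$triangles[, 2], , drop = FALSE] -
    v[mesh$triangles[, 1], , drop = FALSE]
  e2 <- v[mesh$triangles[, 3], , drop = FALSE] -
    v[mesh$triangles[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Check that a triangle mesh is closed
#'
#' A closed oriented surface uses every undirected edge exactly twice
#' (once per direction).
#' @param mesh a \code{tri_mesh}.
#' @return \code{TRUE} if closed.
#' @export
mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(FALSE)
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(key) == 2L)
}

#' Rigidly transform a mesh
#' @param mesh a \code{tri_mesh}.
#' @param transform a \code{\link{rigid_transform}}.
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_rigid(transform, mesh$vertices)
  mesh
}

# Merge duplicated vertices of a triangle soup into an indexed mesh.
weld_mesh <- function(tri_coords, tol = 1e-6) {
  n <- nrow(tri_coords)
  key <- paste(round(tri_coords[, 1] / tol), round(tri_coords[, 2] / tol),
               round(tri_coords[, 3] / tol))
  uid <- match(key, key)
  keep <- !duplicated(uid)
  remap <- integer(n)
  remap[which(keep)] <- seq_len(sum(keep))
  vid <- remap[uid]
  tri_mesh(tri_coords[keep, , drop = FALSE],
           matrix(vid, ncol = 3L, byrow = TRUE))
}

# Marching tetrahedra on a uniform cell-centered grid. Each grid cube is
# split into six tetrahedra sharing the main diagonal; each tetrahedron
# crossed by the iso-level emits one or two triangles with vertices
# linearly interpolated along its edges. Triangles are oriented with
# normals pointing from the super-level ("inside") region outwards.
marching_tets <- function(values, dims, origin, spacing, level) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  sxy <- nx * ny
  # lower-corner linear indices of all cubes
  ix <- seq_len(nx - 1L); iy <- seq_len(ny - 1L); iz <- seq_len(nz - 1L)
  base <- rep(ix, times = (ny - 1L) * (nz - 1L)) +
    nx * rep(rep(iy - 1L, each = nx - 1L), times = nz - 1L) +
    sxy * rep(iz - 1L, each = (nx - 1L) * (ny - 1L))
  off <- c(0L, 1L, 1L + nx, nx, sxy, sxy + 1L, sxy + nx + 1L, sxy + nx)
  fmin <- fmax <- values[base + off[1]]
  for (o in off[-1]) {
    fv <- values[base + o]
    fmin <- pmin(fmin, fv); fmax <- pmax(fmax, fv)
  }
  cand <- base[fmin < level & fmax >= level & is.finite(fmin) & is.finite(fmax)]
  if (!length(cand)) return(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))

  # six tetrahedra around the v0-v6 diagonal (corner numbering: bit order
  # x, y, z of the cube corner offsets)
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  coords_of <- function(idx) {
    i0 <- idx - 1L
    cbind(origin[1] + spacing * (i0 %% nx),
          origin[2] + spacing * ((i0 %/% nx) %% ny),
          origin[3] + spacing * (i0 %/% sxy))
  }
  out <- vector("list", 6L)
  for (t in seq_len(6L)) {
    vi <- cbind(cand + off[tets[t, 1]], cand + off[tets[t, 2]],
                cand + off[tets[t, 3]], cand + off[tets[t, 4]])
    F <- matrix(values[vi], ncol = 4L)
    ins <- F > level
    pat <- ins %*% c(1L, 2L, 4L, 8L)
    keep <- pat > 0L & pat < 15L
    if (!any(keep)) next
    vi <- vi[keep, , drop = FALSE]; F <- F[keep, , drop = FALSE]
    pat <- pat[keep]
    out[[t]] <- emit_tet_triangles(vi, F, pat, level, coords_of)
  }
  soup <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(soup) || nrow(soup) == 0L)
    return(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  weld_mesh(soup, tol = spacing * 1e-7)
}

# Emit oriented triangles for a batch of tetrahedra (rows) with the given
# inside patterns. Returns a 3*ntri x 3 coordinate soup (consecutive rows
# form triangles).
emit_tet_triangles <- function(vi, F, pat, level, coords_of) {
  interp <- function(ia, ib) {
    # point on edge (a, b) where the field crosses the level
    fa <- F[cbind(seq_len(nrow(F)), ia)]
    fb <- F[cbind(seq_len(nrow(F)), ib)]
    pa <- coords_of(vi[cbind(seq_len(nrow(vi)), ia)])
    pb <- coords_of(vi[cbind(seq_len(nrow(vi)), ib)])
    tt <- (level - fa) / (fb - fa)
    pa + tt * (pb - pa)
  }
  singles <- list(`1` = c(1L, 2L, 3L, 4L), `2` = c(2L, 1L, 3L, 4L),
                  `4` = c(3L, 1L, 2L, 4L), `8` = c(4L, 1L, 2L, 3L))
  triples <- list(`14` = c(1L, 2L, 3L, 4L), `13` = c(2L, 1L, 3L, 4L),
                  `11` = c(3L, 1L, 2L, 4L), `7` = c(4L, 1L, 2L, 3L))
  doubles <- list(`3` = c(1L, 2L, 3L, 4L), `5` = c(1L, 3L, 2L, 4L),
                  `9` = c(1L, 4L, 2L, 3L), `6` = c(2L, 3L, 1L, 4L),
                  `10` = c(2L, 4L, 1L, 3L), `12` = c(3L, 4L, 1L, 2L))
  orient <- function(p1, p2, p3, outward) {
    # flip triangles whose normal opposes the outward reference
    n1 <- (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
      (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2])
    n2 <- (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) -
      (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3])
    n3 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
    flip <- n1 * outward[, 1] + n2 * outward[, 2] + n3 * outward[, 3] < 0
    tmp <- p2[flip, , drop = FALSE]
    p2[flip, ] <- p3[flip, , drop = FALSE]
    p3[flip, ] <- tmp
    rbind_interleave(p1, p2, p3)
  }
  rbind_interleave <- function(p1, p2, p3) {
    n <- nrow(p1)
    out <- matrix(0, 3L * n, 3L)
    out[seq(1L, 3L * n, by = 3L), ] <- p1
    out[seq(2L, 3L * n, by = 3L), ] <- p2
    out[seq(3L, 3L * n, by = 3L), ] <- p3
    out
  }
  pieces <- list()
  for (p in names(singles)) {
    rows <- which(pat == as.integer(p))
    if (!length(rows)) next
    o <- singles[[p]]
    sub <- function(m) m[rows, , drop = FALSE]
    Fs <- sub(F); vis <- sub(vi)
    loc_interp <- function(ia, ib) {
      fa <- Fs[, ia]; fb <- Fs[, ib]
      pa <- coords_of(vis[, ia]); pb <- coords_of(vis[, ib])
      pa + ((level - fa) / (fb - fa)) * (pb - pa)
    }
    p1 <- loc_interp(o[1], o[2]); p2 <- loc_interp(o[1], o[3])
    p3 <- loc_interp(o[1], o[4])
    inpt <- coords_of(vis[, o[1]])
    ctr <- (p1 + p2 + p3) / 3
    pieces[[length(pieces) + 1L]] <- orient(p1, p2, p3, ctr - inpt)
  }
  for (p in names(triples)) {
    rows <- which(pat == as.integer(p))
    if (!length(rows)) next
    o <- triples[[p]]  # o[1] is the single OUTSIDE vertex
    Fs <- F[rows, , drop = FALSE]; vis <- vi[rows, , drop = FALSE]
    loc_interp <- function(ia, ib) {
      fa <- Fs[, ia]; fb <- Fs[, ib]
      pa <- coords_of(vis[, ia]); pb <- coords_of(vis[, ib])
      pa + ((level - fa) / (fb - fa)) * (pb - pa)
    }
    p1 <- loc_interp(o[1], o[2]); p2 <- loc_interp(o[1], o[3])
    p3 <- loc_interp(o[1], o[4])
    outpt <- coords_of(vis[, o[1]])
    ctr <- (p1 + p2 + p3) / 3
    pieces[[length(pieces) + 1L]] <- orient(p1, p2, p3, outpt - ctr)
  }
  for (p in names(doubles)) {
    rows <- which(pat == as.integer(p))
    if (!length(rows)) next
    o <- doubles[[p]]  # o[1:2] inside, o[3:4] outside
    Fs <- F[rows, , drop = FALSE]; vis <- vi[rows, , drop = FALSE]
    loc_interp <- function(ia, ib) {
      fa <- Fs[, ia]; fb <- Fs[, ib]
      pa <- coords_of(vis[, ia]); pb <- coords_of(vis[, ib])
      pa + ((level - fa) / (fb - fa)) * (pb - pa)
    }
    q1 <- loc_interp(o[1], o[3]); q2 <- loc_interp(o[1], o[4])
    q3 <- loc_interp(o[2], o[4]); q4 <- loc_interp(o[2], o[3])
    outward <- (coords_of(vis[, o[3]]) + coords_of(vis[, o[4]])) / 2 -
      (coords_of(vis[, o[1]]) + coords_of(vis[, o[2]])) / 2
    pieces[[length(pieces) + 1L]] <- orient(q1, q2, q3, outward)
    pieces[[length(pieces) + 1L]] <- orient(q1, q3, q4, outward)
  }
  do.call(rbind, pieces)
}

#' Unit icosphere mesh
#'
#' Subdivided icosahedron: nearly uniform triangles, convenient for
#' sampling tests and as a comparator surface.
#' @param subdivisions subdivision level (0 = icosahedron).
#' @param radius sphere radius.
#' @param center length-3 center.
#' @return a \code{tri_mesh} with outward orientation.
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    mid <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[key]])) return(mid[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 4L * nf, 3L)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(c, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  m <- tri_mesh(sweep(v * radius, 2L, center, `+`), f)
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

#' Two-half-ellipsoid surface
#'
#' Closed surface made of two half-ellipsoids sharing the equatorial disc
#' plane z = 0: semi-axes (a, a, c_pos) for z > 0 and (a, a, c_neg) for
#' z < 0. This is the shape of the manufacturer-chart ablation model.
#'
#' @param a radial semi-axis (mm).
#' @param c_pos axial semi-axis above the equator (mm).
#' @param c_neg axial semi-axis below the equator (mm).
#' @param n_theta,n_phi angular resolution.
#' @return a closed \code{tri_mesh} with outward orientation.
#' @export
half_ellipsoid_union <- function(a, c_pos, c_neg, n_theta = 48L,
                                 n_phi = 96L) {
  # latitude from -pi/2 (bottom pole) to pi/2 (top pole); the axial
  # semi-axis switches at the equator, continuous (C0) at the seam
  lat <- seq(-pi / 2, pi / 2, length.out = 2L * n_theta + 1L)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  cax <- ifelse(lat >= 0, c_pos, c_neg)
  ring_v <- function(la, cz) {
    cbind(a * cos(la) * cos(phi), a * cos(la) * sin(phi),
          cz * sin(la))
  }
  nlat <- length(lat)
  verts <- list(matrix(c(0, 0, -c_neg), 1L))
  ring_start <- integer(nlat)
  for (i in 2:(nlat - 1L)) {
    ring_start[i] <- 1L + (i - 2L) * n_phi + 1L
    verts[[i]] <- ring_v(lat[i], cax[i])
  }
  top <- 1L + (nlat - 2L) * n_phi + 1L
  verts[[nlat]] <- matrix(c(0, 0, c_pos), 1L)
  V <- do.call(rbind, verts)
  tris <- list()
  # bottom fan
  r1 <- ring_start[2] + 0:(n_phi - 1L)
  tris[[1]] <- cbind(1L, r1, r1[c(2:n_phi, 1L)])
  # bands
  for (i in 2:(nlat - 2L)) {
    ra <- ring_start[i] + 0:(n_phi - 1L)
    rb <- ring_start[i + 1L] + 0:(n_phi - 1L)
    ra2 <- ra[c(2:n_phi, 1L)]; rb2 <- rb[c(2:n_phi, 1L)]
    tris[[length(tris) + 1L]] <- cbind(ra, ra2, rb)
    tris[[length(tris) + 1L]] <- cbind(ra2, rb2, rb)
  }
  # top fan
  rl <- ring_start[nlat - 1L] + 0:(n_phi - 1L)
  tris[[length(tris) + 1L]] <- cbind(rl, top, rl[c(2:n_phi, 1L)])
  m <- tri_mesh(V, do.call(rbind, tris))
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

#' Write a mesh as ASCII PLY
#' @param mesh a \code{tri_mesh}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_ply <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, trim = TRUE), 1L, paste,
                   collapse = " "), con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  invisible(file)
}
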