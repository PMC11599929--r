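# Seeded generators for every input class the analysis modules consume:
# branching trees, soma populations with planted within-region correlation,
# tract bundles with known projection geometry, image blocks with planted
# Gaussian varicosity bumps, and density matrices with planted region modules.
# Every generator is a pure function of (spec, seed): the global RNG state is
# saved and restored around each call.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

# orthonormal basis perpendicular to unit vector d
perp_basis <- function(d) {
  a <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(a - sum(a * d) * d)
  v <- c(d[2L] * u[3L] - d[3L] * u[2L],
         d[3L] * u[1L] - d[1L] * u[3L],
         d[1L] * u[2L] - d[2L] * u[1L])
  cbind(u, v)
}

# unit vector at angle theta (deg) from d, azimuth phi (rad) around it
tilt_vector <- function(d, theta_deg, phi) {
  d <- unit(d)
  uv <- perp_basis(d)
  th <- theta_deg * pi / 180
  unit(cos(th) * d + sin(th) * (cos(phi) * uv[, 1L] + sin(phi) * uv[, 2L]))
}

random_unit <- function() {
  z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

lognormal_pars <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Specification for the synthetic neuron generator
#'
#' @param n_stems number of dendritic stems from the soma.
#' @param branch_len_mean,branch_len_sd mean and SD (um, natural scale) of the
#'   log-normal branch-length distribution.
#' @param bif_prob probability that a finished branch bifurcates.
#' @param bif_angle_mean,bif_angle_sd bifurcation amplitude distribution (deg).
#' @param tortuosity per-step angular jitter SD (deg).
#' @param step growth step length (um).
#' @param max_depth maximum branch order (termination guarantee).
#' @param dend_radius,axon_radius,soma_radius node radii (um).
#' @param axon optional axon spec: list with `tract_length` (um), `n_arbors`,
#'   `arbor_spread` (um), `arbor_sep` (um between distal arbor anchors),
#'   `arbor_branches` (approximate branch count per arbor) and `tract_step`
#'   (node spacing along the tract, um).
#' @return A list of class `neuron_gen_spec`.
#' @export
neuron_gen_spec <- function(n_stems = 4, branch_len_mean = 40, branch_len_sd = 15,
                            bif_prob = 0.7, bif_angle_mean = 60, bif_angle_sd = 15,
                            tortuosity = 8, step = 5, max_depth = 5,
                            dend_radius = 0.5, axon_radius = 0.3, soma_radius = 5,
                            axon = NULL) {
  stopifnot(n_stems >= 1, branch_len_mean > 0, branch_len_sd > 0,
            bif_prob >= 0, bif_prob <= 1, step > 0, max_depth >= 1)
  spec <- as.list(environment())
  class(spec) <- "neuron_gen_spec"
  spec
}

# mutable node accumulator used by the growers
new_swc_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- vector("list", 0L)
  env$tag <- 0L # ground-truth arbor index (0 = soma/dendrite/tract)
  env$tags <- integer()
  env$add <- function(type, pos, radius, parent) {
    id <- length(env$rows) + 1L
    env$rows[[id]] <- c(id, type, pos, radius, parent)
    env$tags[id] <- env$tag
    id
  }
  env
}

grow_branch <- function(b, spec, from_id, pos, dir, depth, type, radius, len = NULL) {
  if (is.null(len)) {
    lp <- lognormal_pars(spec$branch_len_mean, spec$branch_len_sd)
    len <- rlnorm(1, lp$meanlog, lp$sdlog)
  }
  remaining <- len
  cur <- from_id
  while (remaining > 1e-9) {
    h <- min(spec$step, remaining)
    dir <- tilt_vector(dir, abs(rnorm(1, 0, spec$tortuosity)), runif(1, 0, 2 * pi))
    pos <- pos + h * dir
    cur <- b$add(type, pos, radius, cur)
    remaining <- remaining - h
  }
  if (depth < spec$max_depth && runif(1) < spec$bif_prob) {
    amp <- abs(rnorm(1, spec$bif_angle_mean, spec$bif_angle_sd))
    phi <- runif(1, 0, 2 * pi)
    d1 <- tilt_vector(dir, amp / 2, phi)
    d2 <- tilt_vector(dir, amp / 2, phi + pi)
    grow_branch(b, spec, cur, pos, d1, depth + 1L, type, radius)
    grow_branch(b, spec, cur, pos, d2, depth + 1L, type, radius)
  }
  cur
}

#' Generate a synthetic neuron morphology
#'
#' Grows a branching tree from a soma at the origin: dendritic stems with
#' log-normal branch lengths, Gaussian bifurcation amplitudes, and per-step
#' angular jitter (tortuosity); optionally a long axonal tract terminating in
#' one or more compact distal arbors. The same `(spec, seed)` pair always
#' yields the identical tree, and every generated tree passes [validate()].
#'
#' @param spec a [neuron_gen_spec()].
#' @param seed integer seed.
#' @return A [neuron_tree()].
#' @export
synth_neuron <- function(spec, seed) {
  stopifnot(inherits(spec, "neuron_gen_spec"))
  if (spec$n_stems < 1 && is.null(spec$axon)) stop("spec produces zero branches")
  with_seed(seed, {
    b <- new_swc_builder()
    soma <- b$add(SWC_SOMA, c(0, 0, 0), spec$soma_radius, -1L)
    for (i in seq_len(spec$n_stems)) {
      grow_branch(b, spec, soma, c(0, 0, 0), random_unit(), 1L,
                  SWC_BASAL, spec$dend_radius)
    }
    if (!is.null(spec$axon)) grow_axon(b, spec, soma)
    m <- do.call(rbind, b$rows)
    nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                        z = m[, 5], radius = m[, 6], parent = m[, 7])
    neuron_tree(nodes, meta = list(generator = "synth_neuron", seed = seed,
                                   arbor_of = b$tags))
  })
}

grow_axon <- function(b, spec, soma) {
  ax <- spec$axon
  n_arbors <- if (is.null(ax$n_arbors)) 1L else ax$n_arbors
  sep <- if (is.null(ax$arbor_sep)) 2000 else ax$arbor_sep
  spread <- if (is.null(ax$arbor_spread)) 150 else ax$arbor_spread
  nbr <- if (is.null(ax$arbor_branches)) 15L else ax$arbor_branches
  tract_step <- if (is.null(ax$tract_step)) spec$step * 4 else ax$tract_step
  dir <- random_unit()
  pos <- c(0, 0, 0)
  cur <- soma
  anchors <- ax$tract_length - (n_arbors - seq_len(n_arbors)) * sep
  if (any(anchors <= 0)) stop("axon tract too short for requested arbor anchors")
  travelled <- 0
  for (a in seq_len(n_arbors)) {
    # straight-ish tract segment up to the next anchor
    seg <- anchors[a] - travelled
    remaining <- seg
    while (remaining > 1e-9) {
      h <- min(tract_step, remaining)
      dir <- tilt_vector(dir, abs(rnorm(1, 0, 1)), runif(1, 0, 2 * pi))
      pos <- pos + h * dir
      cur <- b$add(SWC_AXON, pos, spec$axon_radius, cur)
      remaining <- remaining - h
    }
    travelled <- anchors[a]
    b$tag <- a
    if (a < n_arbors) {
      # arbor hangs off a side branch so the tract continues through
      side <- tilt_vector(dir, 90, runif(1, 0, 2 * pi))
      grow_arbor(b, spec, cur, pos, side, spread, nbr)
    } else {
      grow_arbor(b, spec, cur, pos, dir, spread, nbr)
    }
    b$tag <- 0L
  }
}

# compact densely branching blob: short branches, high bifurcation pressure
grow_arbor <- function(b, spec, from_id, pos, dir, spread, n_branches) {
  depth_cap <- max(2L, ceiling(log2(n_branches + 1)))
  sub <- spec
  sub$branch_len_mean <- max(spread / depth_cap, 2 * spec$step / 3)
  sub$branch_len_sd <- sub$branch_len_mean / 3
  sub$bif_prob <- 1
  sub$max_depth <- depth_cap
  sub$step <- min(spec$step, sub$branch_len_mean / 2)
  sub$tortuosity <- 15
  grow_branch(b, sub, from_id, pos, dir, 1L, SWC_AXON, spec$axon_radius)
}

#' Specification for the synthetic population generator
#'
#' @param regions list of region descriptors: each a list with `label`,
#'   `center` (3-vector, um), `extent` (3-vector or scalar half-width, um),
#'   `n` (neuron count), `rho` (within-region feature correlation, 0 <= rho < 1)
#'   and optional `shift` (numeric, recycled over features).
#' @param n_features number of features per neuron.
#' @param feature_names optional feature names.
#' @return A list of class `population_gen_spec`.
#' @export
population_gen_spec <- function(regions, n_features = 24, feature_names = NULL) {
  for (r in regions) {
    stopifnot(!is.null(r$label), !is.null(r$center), !is.null(r$n))
    if (r$n <= 0) stop("region '", r$label, "' has n = 0 neurons")
    rho <- if (is.null(r$rho)) 0 else r$rho
    if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  }
  structure(list(regions = regions, n_features = n_features,
                 feature_names = feature_names), class = "population_gen_spec")
}

#' Generate a synthetic soma population with planted feature structure
#'
#' Somas are placed uniformly in each region's extent. Features follow a
#' shared-latent-factor model: within a region each feature is
#' `shift + sqrt(rho) * f_region + sqrt(1 - rho) * eps`, so the expected
#' within-region pairwise Pearson correlation is exactly `rho`.
#'
#' @param spec a [population_gen_spec()].
#' @param seed integer seed.
#' @return List with `somata` (data.frame: id, region, x, y, z) and `features`
#'   (numeric matrix, rows = neurons).
#' @export
synth_population <- function(spec, seed) {
  stopifnot(inherits(spec, "population_gen_spec"))
  p <- spec$n_features
  with_seed(seed, {
    soma_list <- list(); feat_list <- list()
    next_id <- 1L
    # region-level latent factors: unit-variance, mean-centered, and
    # mutually orthogonal across regions, so that "independent types" have
    # exactly uncorrelated shared factors (a random draw would overlap by
    # ~1/sqrt(n_features) and bias cross-type mean correlations)
    R <- length(spec$regions)
    if (p < R + 1L) stop("need n_features > number of regions")
    lat_basis <- qr.Q(qr(cbind(1, matrix(rnorm(p * R), p, R))))[, -1L,
                                                                drop = FALSE]
    lat_basis <- lat_basis * sqrt(p)
    ri <- 0L
    for (r in spec$regions) {
      ri <- ri + 1L
      ext <- rep(r$extent %||% 100, length.out = 3L)
      n <- r$n
      rho <- r$rho %||% 0
      shift <- rep(r$shift %||% 0, length.out = p)
      pos <- cbind(runif(n, r$center[1] - ext[1], r$center[1] + ext[1]),
                   runif(n, r$center[2] - ext[2], r$center[2] + ext[2]),
                   runif(n, r$center[3] - ext[3], r$center[3] + ext[3]))
      latent <- lat_basis[, ri]
      eps <- matrix(rnorm(n * p), n, p)
      f <- sweep(sqrt(rho) * matrix(latent, n, p, byrow = TRUE) +
                   sqrt(1 - rho) * eps, 2L, shift, "+")
      ids <- seq.int(next_id, length.out = n)
      next_id <- next_id + n
      soma_list[[r$label]] <- data.frame(id = ids, region = r$label,
                                         x = pos[, 1], y = pos[, 2], z = pos[, 3])
      feat_list[[r$label]] <- f
    }
    somata <- do.call(rbind, soma_list)
    rownames(somata) <- NULL
    features <- do.call(rbind, feat_list)
    cn <- spec$feature_names %||% paste0("f", seq_len(p))
    dimnames(features) <- list(somata$id, cn)
    list(somata = somata, features = features)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a primary tract object
#'
#' @param points ordered matrix of points soma -> terminus (um).
#' @param neuron_id source neuron id.
#' @param radii optional per-point radii (um).
#' @return A `primary_tract`.
#' @export
primary_tract_obj <- function(points, neuron_id = NA, radii = NULL) {
  points <- as.matrix(points)
  if (polyline_length(points) <= 0) stop("tract must have positive arc length")
  structure(list(points = points, soma = points[1L, ],
                 terminus = points[nrow(points), ], neuron_id = neuron_id,
                 radii = radii),
            class = "primary_tract")
}

#' Generate a synthetic tract bundle with a known projection pattern
#'
#' Soma-end and terminal-end spreads are chosen so the terminal/soma spread
#' ratio is >= 2 for `divergent`, <= 0.5 for `convergent`, and within
#' `[0.8, 1.25]` for `parallel`.
#'
#' @param pattern one of `"convergent"`, `"divergent"`, `"parallel"`.
#' @param n number of tracts (>= 3).
#' @param seed integer seed.
#' @param length bundle length along the projection axis (um).
#' @param spreads optional named list overriding the soma/terminal disc radii.
#' @return List of [primary_tract_obj()] with attributes `pattern`,
#'   `soma_spread`, `terminal_spread`.
#' @export
synth_tract_bundle <- function(pattern = c("convergent", "divergent", "parallel"),
                               n, seed, length = 5000, spreads = NULL) {
  pattern <- match.arg(pattern)
  if (n < 3) stop("need n >= 3 tracts")
  sp <- spreads %||% switch(pattern,
    divergent  = list(soma = 100, term = 800),
    convergent = list(soma = 800, term = 100),
    parallel   = list(soma = 400, term = 400))
  with_seed(seed, {
    tracts <- lapply(seq_len(n), function(i) {
      a0 <- runif(1, 0, 2 * pi); r0 <- sp$soma * sqrt(runif(1))
      a1 <- runif(1, 0, 2 * pi); r1 <- sp$term * sqrt(runif(1))
      p0 <- c(0, r0 * cos(a0), r0 * sin(a0))
      p1 <- c(length, r1 * cos(a1), r1 * sin(a1))
      t <- seq(0, 1, length.out = 50L)
      pts <- outer(1 - t, p0) + outer(t, p1)
      # mild perpendicular wobble; endpoints exact
      w <- 5 * sin(t * pi) * rnorm(1)
      pts[, 2] <- pts[, 2] + w * rnorm(1)
      pts[, 3] <- pts[, 3] + w * rnorm(1)
      pts[1L, ] <- p0; pts[50L, ] <- p1
      primary_tract_obj(pts, neuron_id = i)
    })
    attr(tracts, "pattern") <- pattern
    attr(tracts, "soma_spread") <- sp$soma
    attr(tracts, "terminal_spread") <- sp$term
    tracts
  })
}

#' Specification for the synthetic image-block generator
#'
#' @param dim block shape in voxels (3 integers).
#' @param voxel voxel size (um, isotropic).
#' @param tube_radius baseline tube radius (um).
#' @param fg_intensity intensity on the tube axis away from varicosities.
#' @param background background level.
#' @param varicosities data.frame with columns `arc` (um along the skeleton),
#'   `gain` (amplitude gain >= 1) and `sigma` (um).
#' @param noise optional list: `poisson_scale` (photon scale t; counts are
#'   `rpois(I * t) / t`) and/or `gaussian_sd` (additive read noise).
#' @param bit_depth 8 or 16.
#' @return A list of class `block_gen_spec`.
#' @export
block_gen_spec <- function(dim = c(64L, 64L, 32L), voxel = 1, tube_radius = 1.5,
                           fg_intensity = 100, background = 0,
                           varicosities = NULL, noise = NULL, bit_depth = 8L) {
  if (!is.null(varicosities) && any(varicosities$gain < 1))
    stop("varicosity amplitude gain must be >= 1")
  structure(as.list(environment()), class = "block_gen_spec")
}

# concatenated skeleton polyline of a tree (branch order), with global arc
skeleton_polyline <- function(tree, types = SWC_AXON, spacing = 0.5) {
  branches <- branch_decomposition(tree, types = types)
  pts_all <- NULL
  for (b in branches) {
    pts <- node_xyz(tree, b$rows)
    len <- polyline_length(pts)
    if (len <= 0) next
    k <- max(2L, ceiling(len / spacing) + 1L)
    pts_all <- rbind(pts_all, resample_polyline(pts, k))
  }
  seg <- sqrt(rowSums((pts_all[-1L, , drop = FALSE] -
                       pts_all[-nrow(pts_all), , drop = FALSE])^2))
  list(points = pts_all, arc = c(0, cumsum(seg)))
}

#' Render a synthetic image block around a neurite fragment
#'
#' The skeleton is rendered as a tube of the stated radius and axial
#' intensity; each varicosity adds an isotropic Gaussian bump of the stated
#' sigma and amplitude gain to both the local radius and intensity profile.
#' Optional Poisson shot noise and Gaussian read noise are applied last.
#'
#' @param tree_fragment a [neuron_tree()] whose axon lies inside the block.
#' @param spec a [block_gen_spec()].
#' @param seed integer seed (used only by the noise model).
#' @return List with `image` (3-D array, voxel units), `truth` (data.frame of
#'   planted varicosity positions in um) and `spec`.
#' @export
synth_image_block <- function(tree_fragment, spec, seed = 1) {
  stopifnot(inherits(spec, "block_gen_spec"))
  vx <- spec$voxel
  dims <- as.integer(spec$dim)
  sk <- skeleton_polyline(tree_fragment, types = c(SWC_AXON, SWC_BASAL, SWC_APICAL),
                          spacing = vx / 2)
  total <- max(sk$arc)
  vv <- spec$varicosities
  if (!is.null(vv) && any(vv$arc < 0 | vv$arc > total))
    stop("varicosity arc position outside skeleton arc length (0..", round(total, 2), ")")
  gain_at <- function(s) {
    g <- rep(1, length(s))
    if (!is.null(vv)) for (i in seq_len(nrow(vv)))
      g <- g + (vv$gain[i] - 1) * exp(-(s - vv$arc[i])^2 / (2 * vv$sigma[i]^2))
    g
  }
  img <- array(spec$background, dims)
  rad <- spec$tube_radius * gain_at(sk$arc)
  inten <- spec$fg_intensity * gain_at(sk$arc)
  lim <- dims * vx
  if (any(sk$points < max(rad)) || any(sweep(sk$points, 2L, lim) > -max(rad)))
    stop("fragment does not fit in block")
  for (i in seq_len(nrow(sk$points))) {
    p <- sk$points[i, ]
    r <- rad[i]
    lo <- pmax(1L, floor((p - r) / vx) + 1L)
    hi <- pmin(dims, ceiling((p + r) / vx))
    if (any(lo > hi)) next
    ix <- lo[1L]:hi[1L]; iy <- lo[2L]:hi[2L]; iz <- lo[3L]:hi[3L]
    cx <- (ix - 0.5) * vx - p[1L]; cy <- (iy - 0.5) * vx - p[2L]; cz <- (iz - 0.5) * vx - p[3L]
    d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    inside <- d2 <= r^2
    sub <- img[ix, iy, iz]
    sub[inside] <- pmax(sub[inside], inten[i])
    img[ix, iy, iz] <- sub
  }
  if (!is.null(spec$noise)) {
    img <- with_seed(seed, {
      out <- img
      if (!is.null(spec$noise$poisson_scale)) {
        t <- spec$noise$poisson_scale
        out <- array(rpois(length(out), as.vector(out) * t) / t, dims)
      }
      if (!is.null(spec$noise$gaussian_sd))
        out <- out + array(rnorm(length(out), 0, spec$noise$gaussian_sd), dims)
      out
    })
  }
  maxval <- 2^spec$bit_depth - 1
  img <- array(pmin(maxval, pmax(0, round(img))), dims)
  truth <- if (is.null(vv)) {
    data.frame(x = numeric(), y = numeric(), z = numeric(), arc = numeric())
  } else {
    idx <- vapply(vv$arc, function(a) which.min(abs(sk$arc - a)), integer(1))
    data.frame(x = sk$points[idx, 1L], y = sk$points[idx, 2L],
               z = sk$points[idx, 3L], arc = vv$arc, gain = vv$gain,
               sigma = vv$sigma)
  }
  list(image = img, truth = truth, spec = spec)
}

#' Generate a region-by-brain density matrix with planted modules
#'
#' Each column (brain) is a normalized density vector over regions. Planted
#' modules share a per-brain latent factor so that the cross-brain Spearman
#' correlation within a module is approximately `rho`; regions outside all
#' modules are independent.
#'
#' @param n_regions,n_brains matrix dimensions.
#' @param planted_modules list of `list(regions = <indices>, rho = <value>)`
#'   with disjoint region sets and `rho < 1`.
#' @param seed integer seed.
#' @return Matrix (regions x brains) with columns summing to 1; attribute
#'   `modules` records the planted sets.
#' @export
synth_density_matrix <- function(n_regions, n_brains, planted_modules = list(),
                                 seed = 1) {
  all_m <- unlist(lapply(planted_modules, `[[`, "regions"))
  if (anyDuplicated(all_m)) stop("planted region sets must be disjoint")
  for (m in planted_modules) if (m$rho >= 1) stop("rho must be < 1")
  with_seed(seed, {
    g <- matrix(rnorm(n_regions * n_brains), n_regions, n_brains)
    for (m in planted_modules) {
      z <- rnorm(n_brains)
      g[m$regions, ] <- sqrt(m$rho) * matrix(z, length(m$regions), n_brains,
                                             byrow = TRUE) +
        sqrt(1 - m$rho) * g[m$regions, ]
    }
    # positive densities, monotone in the latent Gaussians (rank structure
    # preserved); the damped exponent keeps column sums from being dominated
    # by single regions, so per-brain normalization stays near-neutral
    d <- exp(g / 2)
    d <- sweep(d, 2L, colSums(d), "/")
    dimnames(d) <- list(paste0("R", seq_len(n_regions)),
                        paste0("brain", seq_len(n_brains)))
    attr(d, "modules") <- planted_modules
    d
  })
}
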